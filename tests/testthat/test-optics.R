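test_that("naperian conversion matches ln(10) * A / L and is linear in A", {
  expect_equal(naperian(0, 0.01), 0)
  expect_equal(naperian(1, 1), log(10))
  expect_equal(naperian(0.230, 0.01), log(10) * 0.230 / 0.01, tolerance = 1e-12) # 52.9595
  a <- naperian(c(0.1, 0.2, 0.4), 0.01)
  expect_equal(naperian(3 * c(0.1, 0.2, 0.4), 0.01), 3 * a)
  expect_error(naperian(0.1, 0), "path_length")
})

test_that("absorbance_at returns grid values exactly and interpolates linearly", {
  sp <- new_spectrum(c(250, 260, 270), c(0.2, 0.1, 0.05))
  expect_equal(absorbance_at(sp, 260), 0.1)
  expect_equal(absorbance_at(sp, 255), 0.15)
  expect_error(absorbance_at(sp, 900), "outside the spectrum coverage")
  expect_error(absorbance_at(sp, 200), "outside")
})

test_that("E2:E3 and E4:E6 match arithmetic and exponential closed forms", {
  flat <- new_spectrum(seq(200, 800, 5), rep(0.3, 121))
  expect_equal(e2_e3(flat), 1.0)
  expect_equal(e4_e6(flat), 1.0)

  # closed form on a pure exponential: ratio = exp(s * delta_lambda)
  sp <- exp_spectrum(a0 = 30, s = 0.018)
  expect_equal(e2_e3(sp), exp(0.018 * 110), tolerance = 1e-9) # 7.2427
  sp2 <- exp_spectrum(a0 = 30, s = 0.015)
  expect_equal(e4_e6(sp2), exp(0.015 * 200), tolerance = 1e-9) # 20.086

  grid <- seq(200, 800, 5)
  direct <- new_spectrum(grid, ifelse(grid == 255, 0.4, ifelse(grid == 365, 0.1, 0.2)))
  expect_equal(e2_e3(direct), 4.0)

  neg <- new_spectrum(grid, ifelse(grid >= 600, 0, 0.2))
  expect_warning(r <- e4_e6(neg), "E4:E6")
  expect_true(is.na(r))
})

test_that("specific absorbance divides the Naperian coefficient by DOC", {
  grid <- seq(200, 800, 5)
  sp <- new_spectrum(grid, rep(0.200, length(grid)))
  expect_equal(suva(sp, 5), log(10) * 0.200 / 0.01 / 5, tolerance = 1e-12) # 9.2103
  # homogeneity: doubling DOC halves the value
  expect_equal(suva(sp, 10), suva(sp, 5) / 2)
  expect_equal(sac350(sp, 5), suva(sp, 5)) # flat spectrum: same A at all wavelengths
  expect_warning(v <- specific_absorbance(sp, 0, 255), "DOC")
  expect_true(is.na(v))
  zero <- new_spectrum(grid, rep(0, length(grid)))
  expect_equal(suva(zero, 5), 0)
})

test_that("spectral slope recovers exact exponentials across the natural S range", {
  for (s in c(0.005, 0.010, 0.0185, 0.025, 0.032)) {
    sp <- exp_spectrum(a0 = 30, s = s)
    fit <- spectral_slope(sp, c(275, 295))
    expect_equal(fit$s, s, tolerance = 1e-6)
    expect_equal(fit$a_ref, 30 * exp(-s * 0), tolerance = 1e-6)
    # nonlinear and log-linear agree on noise-free input
    ll <- spectral_slope(sp, c(275, 295), method = "log_linear")
    expect_equal(fit$s, ll$s, tolerance = 1e-8)
    # deeper-window fit too
    expect_equal(spectral_slope(sp, c(350, 400))$s, s, tolerance = 1e-6)
  }
  # exactly flat spectra make the exponential rate unidentifiable for the
  # nonlinear optimizer; the contract is fall back to log-linear with a warning
  flat <- new_spectrum(seq(200, 800, 5), rep(0.3, 121))
  expect_warning(f0 <- spectral_slope(flat, c(275, 295)), "log-linear")
  expect_equal(f0$s, 0, tolerance = 1e-10)
  expect_equal(f0$method, "log_linear")
})

test_that("slope estimation is unbiased under multiplicative noise", {
  # simulation oracle: mean of repeated noisy fits approaches the true slope
  set.seed(42)
  s_true <- 0.0185
  ests <- vapply(1:200, function(i) {
    sp <- synth_spectrum(30, s_true, grid = seq(250, 450, 5), noise_sigma = 0.01)
    spectral_slope(sp, c(275, 295))$s
  }, numeric(1))
  expect_lt(abs(mean(ests) - s_true) / s_true, 0.01)
})

test_that("slope fit guards: too few points and non-positive coefficients", {
  sp <- exp_spectrum()
  expect_warning(f <- spectral_slope(sp, c(275, 281)), "fewer than 3")
  expect_true(is.na(f$s))
  # negative absorbances inside the window are excluded
  grid <- seq(200, 800, 5)
  a <- 30 * exp(-0.018 * (grid - 275))
  a[grid %in% c(280, 290)] <- -1
  sp2 <- new_spectrum(grid, a * 0.01 / log(10))
  fit <- spectral_slope(sp2, c(275, 295))
  expect_equal(fit$n_points, 3L)
  expect_equal(fit$s, 0.018, tolerance = 1e-6)
})

test_that("slope ratio is 1 for single exponentials and matches independent window fits", {
  sp <- exp_spectrum(a0 = 25, s = 0.021)
  f1 <- spectral_slope(sp, c(275, 295))
  f2 <- spectral_slope(sp, c(350, 400))
  expect_equal(slope_ratio(f1, f2), 1.0, tolerance = 1e-8)
  expect_equal(slope_ratio(0.020, 0.010), 2.0)
  expect_warning(r <- slope_ratio(0.02, 0), "undefined")
  expect_true(is.na(r))

  # sum of two exponentials: oracle = independent refits of each window
  grid <- seq(200, 800, 5)
  a <- 20 * exp(-0.02 * (grid - 275)) + 5 * exp(-0.008 * (grid - 275))
  sp2 <- new_spectrum(grid, a * 0.01 / log(10))
  g1 <- spectral_slope(sp2, c(275, 295))
  g2 <- spectral_slope(sp2, c(350, 400))
  expect_equal(slope_ratio(g1, g2), g1$s / g2$s)
  expect_gt(slope_ratio(g1, g2), 1) # shallower tail slope
})

test_that("ratio indices are scale-invariant; specific coefficients scale linearly", {
  sp <- exp_spectrum(a0 = 30, s = 0.018)
  scaled <- new_spectrum(sp$wavelength_nm, 3.7 * sp$absorbance, sp$path_length_m[1])
  expect_equal(e2_e3(scaled), e2_e3(sp), tolerance = 1e-12)
  expect_equal(e4_e6(scaled), e4_e6(sp), tolerance = 1e-12)
  expect_equal(spectral_slope(scaled, c(275, 295))$s, spectral_slope(sp, c(275, 295))$s,
    tolerance = 1e-8
  )
  expect_equal(suva(scaled, 5), 3.7 * suva(sp, 5), tolerance = 1e-9)
})

test_that("optical_metrics computes the full index set and flags missing coverage", {
  sp <- exp_spectrum(a0 = 30, s = 0.018)
  m <- optical_metrics(sp, doc = 10)
  expect_named(m, c("e2e3", "e4e6", "suva", "sac350", "sac420", "s275_295", "s350_400", "sr"))
  expect_equal(m$s275_295, 0.018, tolerance = 1e-6)
  expect_equal(m$sr, 1, tolerance = 1e-6)
  expect_equal(m$suva, 30 * exp(-0.018 * (255 - 275)) / 10, tolerance = 1e-6)

  short <- exp_spectrum(grid = seq(250, 420, 5))
  expect_warning(m2 <- optical_metrics(short, doc = 10), "E4:E6")
  expect_true(is.na(m2$e4e6))
  expect_false(is.na(m2$suva))
})
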