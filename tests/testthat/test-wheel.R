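test_that("axis fitting records dataset min/max and rejects constant columns", {
  m <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    suva = c(2, 4, 6), s275_295 = c(0.01, 0.02, 0.03),
    hsf = c(20, 50, 80), doc_don = c(10, 60, 110)
  )
  axes <- fit_axes(m)
  expect_equal(axes$min[axes$metric == "suva"], 2)
  expect_equal(axes$max[axes$metric == "suva"], 6)
  expect_equal(axes$angle_deg, c(135, 45, 315, 225))
  m$suva <- 3
  expect_error(fit_axes(m), "suva")
})

test_that("normalization maps endpoints to 0/1, midpoints to 0.5, and is monotone", {
  m <- tibble::tibble(
    sample_id = c("lo", "mid", "hi"),
    suva = c(2, 4, 6), s275_295 = c(0.01, 0.02, 0.03),
    hsf = c(20, 50, 80), doc_don = c(10, 60, 110)
  )
  axes <- fit_axes(m)
  w <- normalize_wheels(m, axes)
  vals <- tidyr::pivot_wider(
    tibble::as_tibble(w)[, c("sample_id", "metric", "value")],
    names_from = "metric", values_from = "value"
  )
  expect_equal(unlist(vals[vals$sample_id == "lo", -1]), c(suva = 0, s275_295 = 0, hsf = 0, doc_don = 0))
  expect_equal(unlist(vals[vals$sample_id == "hi", -1]), c(suva = 1, s275_295 = 1, hsf = 1, doc_don = 1))
  expect_equal(unname(unlist(vals[vals$sample_id == "mid", -1])), rep(0.5, 4))
  # monotone on every axis
  expect_true(all(vals[vals$sample_id == "lo", -1] <= vals[vals$sample_id == "mid", -1]))
})

test_that("out-of-range samples are clipped into [0,1] with a warning", {
  m <- tibble::tibble(
    sample_id = c("a", "b"),
    suva = c(2, 6), s275_295 = c(0.01, 0.03), hsf = c(20, 80), doc_don = c(10, 110)
  )
  axes <- fit_axes(m)
  new <- tibble::tibble(sample_id = "x", suva = 9, s275_295 = 0.005, hsf = 50, doc_don = 60)
  expect_warning(w <- normalize_wheels(new, axes), "clipped")
  expect_true(all(w$value >= 0 & w$value <= 1))
  expect_equal(sum(w$clipped), 2)
})

test_that("samples missing an axis metric get no wheel and are reported", {
  m <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    suva = c(2, 4, 6), s275_295 = c(0.01, NA, 0.03),
    hsf = c(20, 50, 80), doc_don = c(10, 60, 110)
  )
  axes <- fit_axes(m)
  expect_message(w <- normalize_wheels(m, axes), "b")
  expect_setequal(unique(w$sample_id), c("a", "c"))
})

test_that("polygon vertices land on the axes at the trigonometric positions", {
  w <- wheels_from_values(list(s = c(1, 0.5, 0.25, 0.75)))
  v <- wheel_polygon(w, radius = 1)
  r2 <- sqrt(2) / 2
  expect_equal(v$x, c(-1 * r2, 0.5 * r2, 0.25 * r2, -0.75 * r2), tolerance = 1e-12)
  expect_equal(v$y, c(1 * r2, 0.5 * r2, -0.25 * r2, -0.75 * r2), tolerance = 1e-12)

  ones <- wheel_polygon(wheels_from_values(list(s = rep(1, 4))))
  expect_equal(sqrt(ones$x^2 + ones$y^2), rep(1, 4)) # unit square rotated 45 degrees
  zero <- wheel_polygon(wheels_from_values(list(s = rep(0, 4))))
  expect_true(all(zero$x == 0 & zero$y == 0))
})

test_that("shoelace area equals the closed form for orthogonal axes", {
  expect_equal(wheel_area(wheels_from_values(list(s = rep(1, 4))))$area, 2.0)
  expect_equal(wheel_area(wheels_from_values(list(s = rep(0, 4))))$area, 0.0)
  set.seed(31)
  for (i in 1:200) {
    v <- runif(4)
    ar <- wheel_area(wheels_from_values(list(s = v)))$area
    oracle <- 0.5 * sum(v * v[c(2, 3, 4, 1)])
    expect_equal(ar, oracle, tolerance = 1e-12)
  }
})

test_that("area is monotone in each axis value", {
  set.seed(5)
  for (i in 1:50) {
    v <- runif(4)
    base <- wheel_area(wheels_from_values(list(s = v)))$area
    j <- sample(4, 1)
    v2 <- v
    v2[j] <- min(1, v2[j] + runif(1, 0, 1 - v2[j]))
    expect_gte(wheel_area(wheels_from_values(list(s = v2)))$area, base - 1e-12)
  }
})

test_that("wheel distance is a metric: symmetry, identity, triangle inequality", {
  expect_equal(wheel_distance(rep(0, 4), rep(1, 4)), 2.0)
  expect_equal(wheel_distance(c(0.3, 0.5, 0.1, 0.9), c(0.3, 0.5, 0.1, 0.9)), 0)
  set.seed(17)
  for (i in 1:100) {
    a <- runif(4)
    b <- runif(4)
    c <- runif(4)
    expect_equal(wheel_distance(a, b), wheel_distance(b, a))
    expect_lte(wheel_distance(a, c), wheel_distance(a, b) + wheel_distance(b, c) + 1e-12)
  }
  w <- wheels_from_values(list(p = runif(4), q = runif(4)))
  wp <- w[w$sample_id == "p", ]
  wq <- w[w$sample_id == "q", ]
  attr(wp, "axes") <- attr(w, "axes")
  attr(wq, "axes") <- attr(w, "axes")
  expect_equal(wheel_distance(wp, wq), sqrt(sum((wp$value - wq$value)^2)))
  w3 <- wheels_from_values(list(p = runif(3)), metrics = c("a", "b", "c"), angles = c(90, 210, 330))
  expect_error(wheel_distance(wp, w3[w3$sample_id == "p", ]), "axis sets")
})

test_that("classification returns exact template hits, cutoffs, and logged ties", {
  tmpl <- end_member_templates()
  gw <- tmpl[tmpl$template == "groundwater", ]
  w <- wheels_from_values(list(exact_gw = gw$value))
  cls <- classify_wheels(w, tmpl)
  expect_equal(cls$class, "groundwater")
  expect_equal(cls$distance, 0)

  two <- tmpl[tmpl$template %in% c("groundwater", "photolyzed"), ]
  midpoint <- (two$value[two$template == "groundwater"] +
    two$value[two$template == "photolyzed"]) / 2
  wm <- wheels_from_values(list(mid = midpoint))
  expect_message(cm <- classify_wheels(wm, two, cutoff = Inf), "equidistant")
  expect_equal(cm$class, "groundwater") # first in template order

  far <- wheels_from_values(list(far = c(1, 1, 0, 1)))
  cf <- classify_wheels(far, two, cutoff = 0.2)
  expect_equal(cf$class, "intermediate")
  expect_gt(cf$distance, 0.2)
})

test_that("degradation direction vectors match the known process signatures", {
  ph <- degradation_shift("photolysis")
  expect_equal(ph$direction[ph$metric == "s275_295"], 1)
  expect_equal(sum(ph$direction == 1), 1) # exactly one rising axis
  expect_equal(sum(ph$direction == -1), 3) # the rest fall

  mic <- degradation_shift("microbial")
  expect_equal(mic$direction[mic$metric == "suva"], 1)
  expect_equal(mic$direction[mic$metric == "doc_don"], -1)
  expect_equal(sum(mic$direction == 0), 2) # S_275-295 and HSF untouched
  expect_setequal(mic$metric[mic$direction == 0], c("s275_295", "hsf"))

  expect_error(degradation_shift("thermal"), "thermal")
})

test_that("normalized shape is invariant to affine rescaling of a metric column", {
  m <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    suva = c(2, 4, 6), s275_295 = c(0.01, 0.02, 0.03),
    hsf = c(20, 50, 80), doc_don = c(10, 60, 110)
  )
  w1 <- normalize_wheels(m, fit_axes(m))
  m2 <- m
  m2$hsf <- 10 * m2$hsf + 5 # same affine map applied to samples and reference
  w2 <- normalize_wheels(m2, fit_axes(m2))
  expect_equal(w1$value, w2$value, tolerance = 1e-12)
  expect_equal(wheel_area(w1)$area, wheel_area(w2)$area, tolerance = 1e-12)
})

test_that("bounds round-trip through CSV and support k-axis wheels", {
  dir <- withr::local_tempdir()
  m <- tibble::tibble(
    sample_id = c("a", "b"),
    suva = c(2, 6), s275_295 = c(0.01, 0.03), hsf = c(20, 80), doc_don = c(10, 110)
  )
  axes <- fit_axes(m)
  p <- file.path(dir, "bounds.csv")
  write_bounds(axes, p)
  axes2 <- read_bounds(p)
  expect_equal(as.data.frame(axes2), as.data.frame(axes), tolerance = 1e-12)
  w1 <- normalize_wheels(m, axes)
  w2 <- normalize_wheels(m, axes2)
  expect_equal(w1$value, w2$value)

  # three-axis wheel
  a3 <- manual_axes(c("x", "y", "z"), c(0, 0, 0), c(1, 1, 1))
  m3 <- tibble::tibble(sample_id = "s", x = 0.5, y = 0.25, z = 1)
  w3 <- normalize_wheels(m3, a3)
  expect_equal(nrow(w3), 3)
  expect_error(manual_axes(c("x", "y"), c(0, 0), c(1, 1)), "3 axes|length")
})
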