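#' Naperian absorption coefficient
#'
#' Converts decadal absorbance measured over a cuvette of length `path_length_m`
#' into the Naperian (base-e) absorption coefficient \eqn{a = \ln(10) \, A / L}
#' in units of inverse metres.
#'
#' @param absorbance Decadal absorbance (unitless), possibly a vector. Negative
#'   values are allowed (instrument noise near the detection limit) and yield
#'   negative coefficients; downstream index functions guard against them.
#' @param path_length_m Cuvette path length in metres (a 1 cm cuvette is 0.01).
#' @return Numeric vector of absorption coefficients, m^-1.
#' @examples
#' naperian(0.230, 0.01)
#' @export
naperian <- function(absorbance, path_length_m) {
  if (any(!is.finite(path_length_m)) || any(path_length_m <= 0)) {
    abort("`path_length_m` must be finite and > 0.")
  }
  log(10) * absorbance / path_length_m
}

#' Construct a single-sample absorbance spectrum
#'
#' A spectrum is a plain tibble with columns `wavelength_nm`, `absorbance`
#' (decadal) and `path_length_m`; every optics function accepts one.
#'
#' @param wavelength_nm Strictly increasing wavelengths, nm.
#' @param absorbance Decadal absorbance, same length, all finite.
#' @param path_length_m Cuvette length in metres (scalar).
#' @return A tibble with one row per wavelength.
#' @export
new_spectrum <- function(wavelength_nm, absorbance, path_length_m = 0.01) {
  stopifnot(length(wavelength_nm) == length(absorbance), length(path_length_m) == 1)
  if (is.unsorted(wavelength_nm, strictly = TRUE)) {
    abort("`wavelength_nm` must be strictly increasing.")
  }
  if (any(!is.finite(absorbance))) abort("All absorbance values must be finite.")
  if (!is.finite(path_length_m) || path_length_m <= 0) abort("`path_length_m` must be > 0.")
  tibble::tibble(
    wavelength_nm = as.numeric(wavelength_nm),
    absorbance = as.numeric(absorbance),
    path_length_m = as.numeric(path_length_m)
  )
}

check_spectrum <- function(spectrum) {
  needed <- c("wavelength_nm", "absorbance", "path_length_m")
  missing <- setdiff(needed, names(spectrum))
  if (length(missing)) {
    abort(paste0("Spectrum is missing column(s): ", paste(missing, collapse = ", ")))
  }
  spectrum
}

#' Decadal absorbance at a wavelength
#'
#' Returns the tabulated value when `lambda_nm` falls on the measurement grid
#' and interpolates linearly between the bracketing points otherwise.
#'
#' @param spectrum Spectrum tibble (see [new_spectrum()]).
#' @param lambda_nm Query wavelength, nm; must lie within the spectrum coverage.
#' @return Decadal absorbance at `lambda_nm`.
#' @export
absorbance_at <- function(spectrum, lambda_nm) {
  spectrum <- check_spectrum(spectrum)
  wl <- spectrum$wavelength_nm
  if (lambda_nm < min(wl) || lambda_nm > max(wl)) {
    abort(sprintf(
      "Wavelength %g nm is outside the spectrum coverage [%g, %g] nm.",
      lambda_nm, min(wl), max(wl)
    ))
  }
  approx(wl, spectrum$absorbance, xout = lambda_nm, method = "linear", ties = "ordered")$y
}

#' Absorbance ratios E2:E3 and E4:E6
#'
#' `e2_e3()` is A255 / A365, inversely related to molecular size; `e4_e6()` is
#' A465 / A665, a humification / molecular-weight proxy. Both are identical
#' whether computed from decadal or Naperian values. A non-positive
#' denominator yields `NA` with a warning rather than an unstable ratio.
#'
#' @param spectrum Spectrum tibble.
#' @return A single ratio, or `NA_real_` when undefined.
#' @export
e2_e3 <- function(spectrum) {
  absorbance_ratio(spectrum, 255, 365, "E2:E3")
}

#' @rdname e2_e3
#' @export
e4_e6 <- function(spectrum) {
  absorbance_ratio(spectrum, 465, 665, "E4:E6")
}

absorbance_ratio <- function(spectrum, lambda_num, lambda_den, label) {
  num <- absorbance_at(spectrum, lambda_num)
  den <- absorbance_at(spectrum, lambda_den)
  if (!is.finite(den) || den <= 0) {
    warn(sprintf("%s undefined: absorbance at %g nm is <= 0; returning NA.", label, lambda_den))
    return(NA_real_)
  }
  num / den
}

#' DOC-specific absorption coefficients (SUVA, SAC350, SAC420)
#'
#' The Naperian absorption coefficient at `lambda_nm` divided by the DOC
#' concentration: \eqn{\ln(10) A_\lambda / (L \cdot [DOC])}, in L mg^-1 m^-1.
#' `suva()` evaluates at 255 nm, `sac350()` at 350 nm and `sac420()` at
#' 420 nm. Note the ln(10) factor is included, so `suva()` is a Naperian
#' specific absorbance; conventions that report decadal SUVA254 omit it and
#' give values ~2.3x smaller.
#'
#' @param spectrum Spectrum tibble.
#' @param doc DOC concentration, mg C/L; must be > 0.
#' @param lambda_nm Wavelength, nm.
#' @return Specific absorption coefficient, L mg^-1 m^-1, or `NA` when
#'   `doc` is not positive.
#' @export
specific_absorbance <- function(spectrum, doc, lambda_nm) {
  spectrum <- check_spectrum(spectrum)
  if (!is.finite(doc) || doc <= 0) {
    warn(sprintf("Specific absorbance at %g nm undefined: DOC <= 0 or missing; returning NA.", lambda_nm))
    return(NA_real_)
  }
  a <- naperian(absorbance_at(spectrum, lambda_nm), spectrum$path_length_m[1])
  a / doc
}

#' @rdname specific_absorbance
#' @export
suva <- function(spectrum, doc) specific_absorbance(spectrum, doc, 255)

#' @rdname specific_absorbance
#' @export
sac350 <- function(spectrum, doc) specific_absorbance(spectrum, doc, 350)

#' @rdname specific_absorbance
#' @export
sac420 <- function(spectrum, doc) specific_absorbance(spectrum, doc, 420)

#' Exponential spectral slope of the absorption spectrum
#'
#' Fits \eqn{a(\lambda) = a_{ref} e^{-S (\lambda - \lambda_{ref})}} to the
#' Naperian absorption coefficients inside a wavelength window (endpoints
#' inclusive). `S` is reported positive for a normally decaying spectrum. The
#' default is a nonlinear least-squares fit on the coefficients themselves;
#' `method = "log_linear"` instead regresses \eqn{\ln a} on \eqn{\lambda}
#' by ordinary least squares, which is useful as a cross-check (the two agree
#' exactly on noise-free exponential spectra). Points with a non-positive
#' coefficient are excluded (the log is undefined there and such points sit at
#' the instrument noise floor). If the nonlinear fit fails to converge the
#' function falls back to the log-linear estimate with a warning.
#'
#' @param spectrum Spectrum tibble.
#' @param window Length-2 numeric, fitting window in nm, e.g. `c(275, 295)`.
#' @param lambda_ref Reference wavelength for the amplitude; defaults to the
#'   lower window edge.
#' @param method `"nonlinear"` (default) or `"log_linear"`.
#' @return A one-row tibble of class `dom_slope_fit` with columns `s` (nm^-1),
#'   `a_ref` (m^-1), `window_lo`, `window_hi`, `rss`, `n_points`, `method`.
#'   All-`NA` fit (with a warning) when fewer than 3 usable points remain.
#' @examples
#' sp <- new_spectrum(seq(250, 450, 5), 0.3 * exp(-0.018 * (seq(250, 450, 5) - 275)))
#' spectral_slope(sp, c(275, 295))
#' @export
spectral_slope <- function(spectrum, window = c(275, 295), lambda_ref = window[1],
                           method = c("nonlinear", "log_linear")) {
  method <- match.arg(method)
  spectrum <- check_spectrum(spectrum)
  stopifnot(length(window) == 2, window[1] < window[2])

  in_win <- spectrum$wavelength_nm >= window[1] & spectrum$wavelength_nm <= window[2]
  wl <- spectrum$wavelength_nm[in_win]
  a <- naperian(spectrum$absorbance[in_win], spectrum$path_length_m[1])
  usable <- is.finite(a) & a > 0
  wl <- wl[usable]
  a <- a[usable]

  if (length(a) < 3) {
    warn(sprintf(
      "Spectral slope over [%g, %g] nm: fewer than 3 usable (positive) points; returning NA.",
      window[1], window[2]
    ))
    return(slope_fit_na(window, method))
  }

  # log-linear start / cross-check fit
  ll <- lm(log(a) ~ I(wl - lambda_ref))
  s_ll <- -coef(ll)[[2]]
  aref_ll <- exp(coef(ll)[[1]])

  if (method == "log_linear") {
    resid <- a - aref_ll * exp(-s_ll * (wl - lambda_ref))
    return(slope_fit(s_ll, aref_ll, window, sum(resid^2), length(a), "log_linear"))
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      a ~ aref * exp(-s * (wl - lambda_ref)),
      start = list(aref = aref_ll, s = s_ll),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn(sprintf(
      "Nonlinear slope fit over [%g, %g] nm did not converge; using the log-linear estimate.",
      window[1], window[2]
    ))
    resid <- a - aref_ll * exp(-s_ll * (wl - lambda_ref))
    return(slope_fit(s_ll, aref_ll, window, sum(resid^2), length(a), "log_linear"))
  }
  est <- coef(fit)
  slope_fit(est[["s"]], est[["aref"]], window, sum(stats::resid(fit)^2), length(a), "nonlinear")
}

slope_fit <- function(s, a_ref, window, rss, n_points, method) {
  out <- tibble::tibble(
    s = s, a_ref = a_ref,
    window_lo = window[1], window_hi = window[2],
    rss = rss, n_points = as.integer(n_points), method = method
  )
  class(out) <- c("dom_slope_fit", class(out))
  out
}

slope_fit_na <- function(window, method) {
  slope_fit(NA_real_, NA_real_, window, NA_real_, 0L, method)
}

#' Slope ratio S_R
#'
#' Ratio of the spectral slope over 275--295 nm to the slope over 350--400 nm,
#' an integrative, dimensionless indicator inversely related to overall
#' molecular weight.
#'
#' @param fit_275_295,fit_350_400 Slope fits from [spectral_slope()] (or bare
#'   numeric slopes).
#' @return `S_275-295 / S_350-400`, or `NA` with a warning when the
#'   denominator slope is zero or missing.
#' @export
slope_ratio <- function(fit_275_295, fit_350_400) {
  s1 <- if (is.data.frame(fit_275_295)) fit_275_295$s[1] else fit_275_295
  s2 <- if (is.data.frame(fit_350_400)) fit_350_400$s[1] else fit_350_400
  if (!is.finite(s1) || !is.finite(s2) || s2 == 0) {
    warn("Slope ratio undefined (missing fit or zero denominator slope); returning NA.")
    return(NA_real_)
  }
  s1 / s2
}

#' All absorbance-derived composition metrics for one spectrum
#'
#' Convenience wrapper computing E2:E3, E4:E6, SUVA, SAC350, SAC420 (given a
#' DOC concentration), the two spectral slopes and the slope ratio.
#'
#' @param spectrum Spectrum tibble.
#' @param doc DOC concentration (mg C/L) for the specific coefficients, or
#'   `NA` to leave them missing.
#' @return One-row tibble with columns `e2e3`, `e4e6`, `suva`, `sac350`,
#'   `sac420`, `s275_295`, `s350_400`, `sr`. Metrics whose wavelengths fall
#'   outside the spectrum coverage are `NA` with a warning.
#' @export
optical_metrics <- function(spectrum, doc = NA_real_) {
  spectrum <- check_spectrum(spectrum)
  rng <- range(spectrum$wavelength_nm)
  cov <- function(lo, hi = lo) rng[1] <= lo && rng[2] >= hi

  safe <- function(expr, label) {
    if (!isTRUE(expr$ok)) {
      warn(sprintf("%s not computed: spectrum does not cover %s nm.", label, expr$need))
      return(NA_real_)
    }
    expr$fun()
  }
  want <- function(ok, need, fun) list(ok = ok, need = need, fun = fun)

  s1 <- if (cov(275, 295)) spectral_slope(spectrum, c(275, 295)) else {
    warn("S_275-295 not computed: spectrum does not cover 275-295 nm.")
    slope_fit_na(c(275, 295), "nonlinear")
  }
  s2 <- if (cov(350, 400)) spectral_slope(spectrum, c(350, 400)) else {
    warn("S_350-400 not computed: spectrum does not cover 350-400 nm.")
    slope_fit_na(c(350, 400), "nonlinear")
  }
  sr <- if (is.finite(s1$s) && is.finite(s2$s) && s2$s != 0) s1$s / s2$s else {
    warn("Slope ratio undefined (missing fit or zero denominator slope); returning NA.")
    NA_real_
  }

  doc_ok <- is.finite(doc) && doc > 0
  if (!doc_ok && !is.na(doc)) {
    warn("DOC <= 0; specific absorption coefficients returned as NA.")
  }
  spec_abs <- function(lambda) {
    if (!cov(lambda)) {
      warn(sprintf("Specific absorbance at %g nm not computed: outside spectrum coverage.", lambda))
      return(NA_real_)
    }
    if (!doc_ok) return(NA_real_)
    specific_absorbance(spectrum, doc, lambda)
  }

  tibble::tibble(
    e2e3 = safe(want(cov(255) && cov(365), "255 and 365", function() e2_e3(spectrum)), "E2:E3"),
    e4e6 = safe(want(cov(465) && cov(665), "465 and 665", function() e4_e6(spectrum)), "E4:E6"),
    suva = spec_abs(255),
    sac350 = spec_abs(350),
    sac420 = spec_abs(420),
    s275_295 = s1$s,
    s350_400 = s2$s,
    sr = sr
  )
}
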