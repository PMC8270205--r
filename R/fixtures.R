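#' Synthetic single-exponential absorbance spectrum
#'
#' Generates a decadal absorbance spectrum from the exponential CDOM model
#' \eqn{a(\lambda) = a_0 e^{-s(\lambda - 275)}} (Naperian, m^-1), converted
#' to decadal absorbance over the cuvette length and multiplied by lognormal
#' noise \eqn{e^{\epsilon}}, \eqn{\epsilon \sim N(0, \sigma^2)}. Lognormal
#' noise keeps absorbance positive and mimics relative instrument error.
#' With `noise_sigma = 0` the spectrum is exactly exponential and
#' [spectral_slope()] recovers `s` to machine precision.
#'
#' @param a0 Naperian absorption coefficient at 275 nm, m^-1 (> 0).
#' @param s Spectral slope, nm^-1 (0 gives a flat Naperian spectrum).
#' @param grid Wavelength grid, nm, within 200-800; default 5 nm steps.
#' @param noise_sigma Lognormal sigma of the multiplicative noise (0 = none).
#' @param seed Optional integer seed for reproducibility.
#' @param path_length_m Cuvette length, m.
#' @return A spectrum tibble (see [new_spectrum()]).
#' @export
synth_spectrum <- function(a0, s, grid = seq(200, 800, by = 5), noise_sigma = 0,
                           seed = NULL, path_length_m = 0.01) {
  stopifnot(a0 > 0, noise_sigma >= 0)
  if (min(grid) < 200 || max(grid) > 800) abort("grid must lie within 200-800 nm.")
  if (!is.null(seed)) set.seed(seed)
  a <- a0 * exp(-s * (grid - 275))
  A <- a * path_length_m / log(10)
  if (noise_sigma > 0) {
    A <- A * exp(rnorm(length(grid), 0, noise_sigma))
  }
  new_spectrum(grid, A, path_length_m)
}

#' Default synthetic study conditions
#'
#' Cluster parameters for the two DOM end members the generator emulates.
#' `groundwater_like` has high SUVA, low spectral slope, high HSF and high
#' DOC:DON; `photolyzed_like` the converse. Means and spreads are chosen so
#' that samples fall inside the ranges reported for natural waters at
#' continental scale (SUVA 1.1-21 L mg^-1 m^-1, slope 0.005-0.032 nm^-1,
#' DOC:DON 9-124, HSF 14-85%), with the clusters sitting toward the
#' respective extremes.
#'
#' @return Nested list of per-cluster metric means/sds plus shared settings
#'   (`noise_sigma`, `path_length_m`, `grid`).
#' @export
default_cluster_params <- function() {
  list(
    groundwater_like = list(
      suva = c(mean = 9, sd = 1.2),
      s275_295 = c(mean = 0.008, sd = 0.0015),
      hsf = c(mean = 72, sd = 5),
      doc_don = c(mean = 90, sd = 12),
      doc = c(mean = 30, sd = 8),
      hs_mw = c(mean = 750, sd = 60)
    ),
    photolyzed_like = list(
      suva = c(mean = 2.5, sd = 0.6),
      s275_295 = c(mean = 0.028, sd = 0.002),
      hsf = c(mean = 25, sd = 5),
      doc_don = c(mean = 15, sd = 3),
      doc = c(mean = 5, sd = 1.5),
      hs_mw = c(mean = 430, sd = 50)
    ),
    ranges = list(
      suva = c(1.1, 21), s275_295 = c(0.005, 0.032),
      hsf = c(14, 85), doc_don = c(9, 124), doc = c(0.1, 273)
    ),
    noise_sigma = 0.01,
    path_length_m = 0.01,
    grid = seq(200, 800, by = 5)
  )
}

rnorm_in <- function(n, par, range) {
  pmin(range[2], pmax(range[1], rnorm(n, par[["mean"]], par[["sd"]])))
}

#' Generate a two-cluster synthetic DOM dataset
#'
#' Draws per-sample target metrics (SUVA, S_275-295, HSF, DOC:DON, DOC) from
#' the groundwater-like and photolyzed-like clusters, then back-solves the
#' raw inputs so that recomputing the metrics through the pipeline returns
#' the targets (within the spectral noise): the spectrum is a noisy single
#' exponential whose amplitude is set from the target SUVA and DOC; DON is
#' set from the target DOC:DON and TDN assembled from DON plus small
#' inorganic-N draws; LC-OCD fractions share out the non-HSF remainder.
#' Ground-truth cluster labels are returned for recovery tests.
#'
#' @param n_per_cluster Samples per cluster (default 50).
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @param params Study conditions; see [default_cluster_params()].
#' @param out_dir If non-`NULL`, the four input CSVs plus `truth.csv` are
#'   written there (creating the directory) with deterministic content.
#' @return List with tibbles `spectra`, `chem`, `lcocd`, `meta`, `truth`
#'   (`sample_id`, `cluster`, and the target metric columns). `meta` assigns
#'   sites "GW1"/"GW2" (groundwater setting) and "SW1"/"SW2" (pond/lake).
#' @export
synth_dataset <- function(n_per_cluster = 50, seed, params = default_cluster_params(),
                          out_dir = NULL) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory for synth_dataset().")
  set.seed(seed)
  clusters <- c("groundwater_like", "photolyzed_like")

  truth <- purrr::map_dfr(clusters, function(cl) {
    p <- params[[cl]]
    r <- params$ranges
    n <- n_per_cluster
    tibble::tibble(
      cluster = cl,
      suva = rnorm_in(n, p$suva, r$suva),
      s275_295 = rnorm_in(n, p$s275_295, r$s275_295),
      hsf = rnorm_in(n, p$hsf, r$hsf),
      doc_don = rnorm_in(n, p$doc_don, r$doc_don),
      doc = rnorm_in(n, p$doc, r$doc),
      hs_mw = rnorm(n, p$hs_mw[["mean"]], p$hs_mw[["sd"]])
    )
  })
  n_tot <- nrow(truth)
  truth$sample_id <- sprintf("S%03d", seq_len(n_tot))

  # --- spectra: amplitude from target SUVA x DOC (Naperian a at 255 nm)
  # a(lambda) = a275 e^{-s(lambda-275)}  =>  a275 = a255 e^{-20 s}
  a255 <- truth$suva * truth$doc
  a275 <- a255 * exp(-20 * truth$s275_295)
  spectra <- purrr::map_dfr(seq_len(n_tot), function(i) {
    sp <- synth_spectrum(
      a0 = a275[i], s = truth$s275_295[i], grid = params$grid,
      noise_sigma = params$noise_sigma, path_length_m = params$path_length_m
    )
    dplyr::bind_cols(tibble::tibble(sample_id = truth$sample_id[i]), sp)
  })

  # --- chemistry back-solved from target DOC:DON
  don_target <- truth$doc * ATOMIC_MASS_N / (ATOMIC_MASS_C * truth$doc_don)
  no3 <- runif(n_tot, 0.01, 0.30)
  no2 <- runif(n_tot, 0.001, 0.02)
  nh4 <- runif(n_tot, 0.01, 0.20)
  chem <- tibble::tibble(
    sample_id = truth$sample_id,
    doc_mgC_L = truth$doc,
    tdn_mgN_L = don_target + no3 + no2 + nh4,
    no3_mgN_L = no3, no2_mgN_L = no2, nh4_mgN_L = nh4
  )

  # --- LC-OCD: split the non-humic remainder into the four minor fractions,
  # leaving ~5% chromatographically unresolved
  rest <- (100 - truth$hsf) * 0.95
  w <- cbind(
    bp = runif(n_tot, 0.5, 1.5) * 0.15,
    bb = runif(n_tot, 0.5, 1.5) * 0.40,
    lmwn = runif(n_tot, 0.5, 1.5) * 0.35,
    lmwa = runif(n_tot, 0.5, 1.5) * 0.10
  )
  w <- w / rowSums(w)
  lcocd <- tibble::tibble(
    sample_id = truth$sample_id,
    bp_pct = rest * w[, "bp"],
    hsf_pct = truth$hsf,
    bb_pct = rest * w[, "bb"],
    lmwn_pct = rest * w[, "lmwn"],
    lmwa_pct = rest * w[, "lmwa"],
    hs_mw_g_mol = truth$hs_mw
  )

  # --- metadata: two sites per cluster, settings matching the cluster
  gw <- truth$cluster == "groundwater_like"
  site <- character(n_tot)
  setting <- character(n_tot)
  site[gw] <- rep_len(c("GW1", "GW2"), sum(gw))
  setting[gw] <- rep_len(c("groundwater", "seep"), sum(gw))
  site[!gw] <- rep_len(c("SW1", "SW2"), sum(!gw))
  setting[!gw] <- rep_len(c("pond", "lake"), sum(!gw))
  meta <- tibble::tibble(
    sample_id = truth$sample_id,
    site = site,
    hydro_setting = setting,
    date = as.Date("2019-06-01") + (seq_len(n_tot) %% 90)
  )

  truth <- truth[, c("sample_id", "cluster", "suva", "s275_295", "hsf", "doc_don", "doc", "hs_mw")]
  out <- list(spectra = spectra, chem = chem, lcocd = lcocd, meta = meta, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(spectra, file.path(out_dir, "spectra.csv"))
    readr::write_csv(chem, file.path(out_dir, "chem.csv"))
    readr::write_csv(lcocd, file.path(out_dir, "lcocd.csv"))
    readr::write_csv(meta, file.path(out_dir, "meta.csv"))
    readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  }
  out
}
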