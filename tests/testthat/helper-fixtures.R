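# Shared fixtures, generated in code.

# Exact single-exponential spectrum: a(lambda) = a0 * exp(-s * (lambda - 275))
exp_spectrum <- function(a0 = 30, s = 0.0185, grid = seq(200, 800, 5),
                         path_length_m = 0.01) {
  synth_spectrum(a0, s, grid = grid, noise_sigma = 0, path_length_m = path_length_m)
}

# Small three-sample input bundle written as the four CSVs; returns the paths.
write_three_sample_bundle <- function(dir, drop_lcocd_for = NULL) {
  ids <- c("A1", "B2", "C3")
  spectra <- purrr::map_dfr(seq_along(ids), function(i) {
    sp <- exp_spectrum(a0 = 10 * i, s = 0.010 + 0.005 * i)
    dplyr::bind_cols(tibble::tibble(sample_id = ids[i]), sp)
  })
  chem <- tibble::tibble(
    sample_id = ids, doc_mgC_L = c(5, 10, 20), tdn_mgN_L = c(1.0, 0.8, 2.0),
    no3_mgN_L = c(0.30, 0.10, 0.20), no2_mgN_L = c(0.02, 0.01, 0.01),
    nh4_mgN_L = c(0.18, 0.09, 0.19)
  )
  lcocd <- tibble::tibble(
    sample_id = setdiff(ids, drop_lcocd_for),
    bp_pct = 5, hsf_pct = c(60, 40, 30)[seq_along(sample_id)],
    bb_pct = 15, lmwn_pct = 10, lmwa_pct = 3, hs_mw_g_mol = c(700, 550, 480)[seq_along(sample_id)]
  )
  meta <- tibble::tibble(
    sample_id = ids, site = c("YK", "YK", "ELA"),
    hydro_setting = c("groundwater", "pond", "lake"),
    date = as.Date(c("2019-06-01", "2019-07-01", "2019-06-15"))
  )
  paths <- list(
    spectra = file.path(dir, "spectra.csv"), chem = file.path(dir, "chem.csv"),
    lcocd = file.path(dir, "lcocd.csv"), meta = file.path(dir, "meta.csv")
  )
  readr::write_csv(spectra, paths$spectra)
  readr::write_csv(chem, paths$chem)
  readr::write_csv(lcocd, paths$lcocd)
  readr::write_csv(meta, paths$meta)
  paths
}

# A dom_wheels object built directly from normalized values (bypassing bounds),
# for geometry tests. `values` is a named list sample_id -> numeric quadruple.
wheels_from_values <- function(values, metrics = c("suva", "s275_295", "hsf", "doc_don"),
                               angles = c(135, 45, 315, 225)) {
  axes <- manual_axes(metrics, rep(0, length(metrics)), rep(1, length(metrics)), angles)
  tbl <- purrr::map_dfr(names(values), function(id) {
    tibble::tibble(
      sample_id = id, metric = metrics, angle_deg = angles,
      value = values[[id]], clipped = FALSE
    )
  })
  attr(tbl, "axes") <- axes
  class(tbl) <- c("dom_wheels", class(tbl))
  tbl
}
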