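# CSV schemas for the four input files (comma-separated, UTF-8, header row,
# "." decimal). All readers hard-error on non-numeric cells and duplicates.

SPECTRA_COLS <- c(sample_id = "c", wavelength_nm = "d", absorbance = "d", path_length_m = "d")
CHEM_COLS <- c(
  sample_id = "c", doc_mgC_L = "d", tdn_mgN_L = "d",
  no3_mgN_L = "d", no2_mgN_L = "d", nh4_mgN_L = "d"
)
LCOCD_COLS <- c(
  sample_id = "c", bp_pct = "d", hsf_pct = "d", bb_pct = "d",
  lmwn_pct = "d", lmwa_pct = "d", hs_mw_g_mol = "d"
)
META_COLS <- c(sample_id = "c", site = "c", hydro_setting = "c", date = "D")

HYDRO_SETTINGS <- c("groundwater", "pond", "creek", "river", "lake", "seep", "other")

read_checked_csv <- function(path, cols, what) {
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  df <- readr::read_csv(
    path,
    col_types = do.call(readr::cols_only, as.list(cols)),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(names(cols), names(df))
  if (length(missing)) {
    abort(sprintf("%s (%s): missing column(s) %s", what, path, paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(df)
  if (nrow(probs)) {
    p <- probs[1, ]
    abort(sprintf(
      "%s (%s): unparseable cell at row %d, column %d (expected %s, got '%s').",
      what, path, p$row, p$col, p$expected, p$actual
    ))
  }
  df
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(sprintf(
      "%s: duplicated sample_id(s): %s", what, paste(head(dup, 5), collapse = ", ")
    ))
  }
}

#' Read and join the four Composition Wheel input files
#'
#' Reads long-format absorbance spectra, chemistry, LC-OCD size fractions and
#' sample metadata, validates each against its documented schema, and bundles
#' them keyed by `sample_id`. Samples present in some files but not others are
#' retained; the absent block is simply missing for them. Duplicated sample
#' ids within a file, and cells that fail numeric parsing, are hard errors
#' naming the offender.
#'
#' @param spectra_path CSV with columns
#'   `sample_id,wavelength_nm,absorbance,path_length_m` (one row per
#'   wavelength).
#' @param chem_path CSV with columns
#'   `sample_id,doc_mgC_L,tdn_mgN_L,no3_mgN_L,no2_mgN_L,nh4_mgN_L`.
#' @param lcocd_path CSV with columns
#'   `sample_id,bp_pct,hsf_pct,bb_pct,lmwn_pct,lmwa_pct,hs_mw_g_mol`.
#' @param meta_path CSV with columns `sample_id,site,hydro_setting,date`
#'   (ISO-8601 dates).
#' @return An object of class `dom_dataset`: a list with tibbles `spectra`,
#'   `chem`, `lcocd`, `meta` and the character vector `sample_ids` (the union,
#'   in first-appearance order).
#' @export
read_dom_dataset <- function(spectra_path, chem_path, lcocd_path, meta_path) {
  spectra <- read_checked_csv(spectra_path, SPECTRA_COLS, "spectra")
  chem <- read_checked_csv(chem_path, CHEM_COLS, "chemistry")
  lcocd <- read_checked_csv(lcocd_path, LCOCD_COLS, "LC-OCD")
  meta <- read_checked_csv(meta_path, META_COLS, "metadata")

  key <- paste(spectra$sample_id, spectra$wavelength_nm)
  if (anyDuplicated(key)) {
    bad <- spectra$sample_id[duplicated(key)][1]
    abort(sprintf("spectra: duplicated (sample_id, wavelength) rows for sample '%s'.", bad))
  }
  check_unique(chem$sample_id, "chemistry")
  check_unique(lcocd$sample_id, "LC-OCD")
  check_unique(meta$sample_id, "metadata")

  spectra <- dplyr::arrange(spectra, .data$sample_id, .data$wavelength_nm)
  if (any(!is.finite(spectra$absorbance))) abort("spectra: non-finite absorbance value(s).")
  if (any(spectra$path_length_m <= 0)) abort("spectra: path_length_m must be > 0.")

  bad_setting <- setdiff(unique(meta$hydro_setting), HYDRO_SETTINGS)
  if (length(bad_setting)) {
    warn(sprintf(
      "metadata: hydro_setting value(s) outside the vocabulary (%s) recoded to 'other'.",
      paste(bad_setting, collapse = ", ")
    ))
    meta$hydro_setting[meta$hydro_setting %in% bad_setting] <- "other"
  }

  validate_lcocd(lcocd)

  ids <- unique(c(spectra$sample_id, chem$sample_id, lcocd$sample_id, meta$sample_id))
  inform(sprintf(
    "Read %d samples (%d with spectra, %d with chemistry, %d with LC-OCD, %d with metadata).",
    length(ids), dplyr::n_distinct(spectra$sample_id), nrow(chem), nrow(lcocd), nrow(meta)
  ))

  structure(
    list(spectra = spectra, chem = chem, lcocd = lcocd, meta = meta, sample_ids = ids),
    class = "dom_dataset"
  )
}

validate_lcocd <- function(lcocd, tol = 2) {
  fr <- as.matrix(lcocd[, c("bp_pct", "hsf_pct", "bb_pct", "lmwn_pct", "lmwa_pct")])
  out_of_range <- fr < 0 | fr > 100
  if (any(out_of_range, na.rm = TRUE)) {
    abort("LC-OCD: fraction percentage outside [0, 100].")
  }
  tot <- rowSums(fr)
  over <- !is.na(tot) & tot > 100 + tol
  if (any(over)) {
    abort(sprintf(
      "LC-OCD: fractions sum to more than 100%% (+%g tolerance) for sample '%s'.",
      tol, lcocd$sample_id[over][1]
    ))
  }
  invisible(lcocd)
}

#' @export
print.dom_dataset <- function(x, ...) {
  cat(sprintf(
    "<dom_dataset> %d samples | spectra: %d, chem: %d, lcocd: %d, meta: %d\n",
    length(x$sample_ids), dplyr::n_distinct(x$spectra$sample_id),
    nrow(x$chem), nrow(x$lcocd), nrow(x$meta)
  ))
  invisible(x)
}

#' Compute the per-sample composition metric table
#'
#' Derives every composition measure from a joined dataset: the optical
#' indices from each spectrum (E2:E3, E4:E6, SUVA, SAC350, SAC420, the two
#' spectral slopes and S_R), DON and the molar DOC:DON from chemistry, and
#' the LC-OCD fraction columns carried through. Missing input blocks
#' propagate to explicit `NA`s; nothing is imputed or zero-filled.
#'
#' @param dataset A `dom_dataset` from [read_dom_dataset()] (or an equivalent
#'   list of tibbles).
#' @return A tibble with one row per sample: `sample_id`, `doc`, `don`,
#'   `doc_don`, `e2e3`, `e4e6`, `suva`, `sac350`, `sac420`, `s275_295`,
#'   `s350_400`, `sr`, `bp`, `hsf`, `bb`, `lmwn`, `lmwa`, `hs_mw`.
#' @export
compute_metrics <- function(dataset) {
  ids <- dataset$sample_ids %||% unique(c(
    dataset$spectra$sample_id, dataset$chem$sample_id,
    dataset$lcocd$sample_id, dataset$meta$sample_id
  ))

  chem <- dataset$chem |>
    dplyr::mutate(
      don = don(.data$tdn_mgN_L, .data$no3_mgN_L, .data$no2_mgN_L, .data$nh4_mgN_L),
      doc_don = doc_don_ratio(.data$doc_mgC_L, .data$don)
    ) |>
    dplyr::select("sample_id", doc = "doc_mgC_L", "don", "doc_don")

  spec_split <- split(dataset$spectra, dataset$spectra$sample_id)
  optics <- purrr::map_dfr(names(spec_split), function(id) {
    doc_i <- chem$doc[match(id, chem$sample_id)]
    dplyr::bind_cols(
      tibble::tibble(sample_id = id),
      optical_metrics(spec_split[[id]], doc = if (length(doc_i)) doc_i else NA_real_)
    )
  })

  lcocd <- dataset$lcocd |>
    dplyr::select(
      "sample_id", bp = "bp_pct", hsf = "hsf_pct", bb = "bb_pct",
      lmwn = "lmwn_pct", lmwa = "lmwa_pct", hs_mw = "hs_mw_g_mol"
    )

  tibble::tibble(sample_id = ids) |>
    dplyr::left_join(chem, by = "sample_id") |>
    dplyr::left_join(optics, by = "sample_id") |>
    dplyr::left_join(lcocd, by = "sample_id")
}

#' Average metrics over repeated sampling events
#'
#' Sites sampled on multiple dates are collapsed to a single value per
#' (site, hydro_setting) group by the arithmetic mean of each derived metric
#' over its non-missing values. A group in which a metric is missing for
#' every event stays missing. Averaging happens at the metric level, after
#' derivation, not by averaging spectra.
#'
#' @param metrics Metric table from [compute_metrics()].
#' @param meta Metadata tibble with `sample_id`, `site`, `hydro_setting`.
#' @return A tibble keyed by `site` and `hydro_setting` with the averaged
#'   metric columns and `n_events`, the number of contributing samples.
#' @export
average_by_site <- function(metrics, meta) {
  metrics |>
    dplyr::inner_join(
      dplyr::select(meta, "sample_id", "site", "hydro_setting"),
      by = "sample_id"
    ) |>
    dplyr::group_by(.data$site, .data$hydro_setting) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      dplyr::across(
        dplyr::where(is.numeric) & !dplyr::any_of("n_events"),
        ~ {
          v <- .x[!is.na(.x)]
          if (length(v)) mean(v) else NA_real_
        }
      ),
      .groups = "drop"
    )
}

#' Write / read a metric table as CSV
#'
#' Full-precision round-trip: `read_metrics(write_metrics(x, p))` reproduces
#' the values to better than 1e-9. Missing values are written as empty cells.
#'
#' @param metrics Metric table.
#' @param path Output CSV path.
#' @return `write_metrics()` returns `path` invisibly; `read_metrics()`
#'   returns the tibble.
#' @export
write_metrics <- function(metrics, path) {
  readr::write_csv(metrics, path, na = "")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) abort(sprintf("metrics file not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, na = c("", "NA"))
}
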