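#' Dissolved organic nitrogen by difference
#'
#' DON is the total dissolved nitrogen minus the sum of the inorganic nitrogen
#' species (nitrate, nitrite, ammonium), all in mg N/L. A negative difference
#' means the inorganic species over-subtract TDN (analytical error); the value
#' is returned as `NA` with a warning rather than clipped to zero, so no
#' spurious near-zero DOC:DON denominators are fabricated. Any missing input
#' propagates to a missing result.
#'
#' @param tdn,no3,no2,nh4 Concentrations in mg N/L; vectors are recycled by
#'   the usual rules.
#' @return DON in mg N/L (`NA` where undefined).
#' @examples
#' don(1.00, 0.30, 0.02, 0.18)
#' @export
don <- function(tdn, no3, no2, nh4) {
  out <- tdn - (no3 + no2 + nh4)
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    warn(sprintf(
      "DON negative for %d sample(s) (inorganic N exceeds TDN); set to NA.",
      sum(neg)
    ))
    out[neg] <- NA_real_
  }
  out
}

# Standard atomic masses used for the molar conversion.
ATOMIC_MASS_C <- 12.011
ATOMIC_MASS_N <- 14.007

#' Molar DOC:DON ratio
#'
#' Converts the mass concentrations to molar (DOC / 12.011, DON / 14.007) and
#' returns their ratio, a stoichiometric indicator of DOM nitrogen content.
#'
#' @param doc DOC in mg C/L; must be > 0.
#' @param don DON in mg N/L; non-positive or missing values give `NA`.
#' @return Dimensionless molar ratio.
#' @examples
#' doc_don_ratio(6.0055, 0.70035) # 0.5 mM C over 0.05 mM N -> 10
#' @export
doc_don_ratio <- function(doc, don) {
  out <- (doc / ATOMIC_MASS_C) / (don / ATOMIC_MASS_N)
  bad <- !is.na(don) & don <= 0
  if (any(bad)) {
    warn(sprintf("DOC:DON undefined for %d sample(s) with DON <= 0; set to NA.", sum(bad)))
    out[bad] <- NA_real_
  }
  bad_doc <- !is.na(doc) & doc <= 0
  out[bad_doc] <- NA_real_
  out
}
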