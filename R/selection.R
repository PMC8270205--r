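#' Principal components analysis of the composition metric table
#'
#' Restricts to complete cases over the requested columns, centres and scales
#' each column to unit variance, and performs PCA by singular value
#' decomposition of the standardized matrix (equivalently an
#' eigendecomposition of the correlation matrix). Component signs are fixed
#' so that each component's largest-magnitude loading is positive, making
#' results reproducible across platforms. Per-variable contributions to each
#' component and the eigenvalue-weighted combined contribution to PC1+PC2 are
#' attached; the combined statistic
#' \eqn{(c_{j1}\lambda_1 + c_{j2}\lambda_2)/(\lambda_1+\lambda_2)} is the
#' convention used in standard ordination contribution plots.
#'
#' @param metrics Metric table (one row per sample or per site average).
#' @param columns Character vector of metric columns to ordinate; defaults to
#'   every numeric column except identifiers.
#' @return An object of class `dom_pca`: list with `loadings` (variables x
#'   components), `eigenvalues`, `var_explained` (percent, sums to 100),
#'   `scores`, `contributions` (percent, each column sums to 100),
#'   `combined_contrib_12` (percent per variable), `n_complete`, `columns`.
#' @export
run_pca <- function(metrics, columns = NULL) {
  if (is.null(columns)) {
    columns <- setdiff(
      names(metrics)[vapply(metrics, is.numeric, logical(1))],
      c("n_events")
    )
  }
  missing <- setdiff(columns, names(metrics))
  if (length(missing)) {
    abort(sprintf("Column(s) not in the metric table: %s", paste(missing, collapse = ", ")))
  }
  x <- as.data.frame(metrics[, columns])
  cc <- complete.cases(x)
  x <- as.matrix(x[cc, , drop = FALSE])
  if (nrow(x) < length(columns)) {
    abort(sprintf(
      "Only %d complete-case rows for %d columns; PCA needs at least as many rows as columns.",
      nrow(x), length(columns)
    ))
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf(
      "Zero-variance column(s): %s", paste(columns[sds == 0], collapse = ", ")
    ))
  }
  inform(sprintf("PCA on %d complete-case rows x %d variables.", nrow(x), ncol(x)))

  pc <- prcomp(x, center = TRUE, scale. = TRUE)

  # deterministic sign: largest |loading| of each component made positive
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    l <- pc$rotation[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)

  eig <- pc$sdev^2
  var_explained <- 100 * eig / sum(eig)
  contributions <- 100 * sweep(loadings^2, 2, colSums(loadings^2), `/`)
  combined <- (contributions[, 1] * eig[1] + contributions[, 2] * eig[2]) / (eig[1] + eig[2])

  structure(
    list(
      loadings = loadings,
      eigenvalues = eig,
      var_explained = var_explained,
      scores = scores,
      contributions = contributions,
      combined_contrib_12 = combined,
      n_complete = nrow(x),
      columns = columns
    ),
    class = "dom_pca"
  )
}

#' @export
print.dom_pca <- function(x, ...) {
  cat(sprintf(
    "<dom_pca> %d rows x %d variables | PC1+PC2: %.1f%%, PC1-3: %.1f%% of variance\n",
    x$n_complete, length(x$columns),
    sum(x$var_explained[1:2]), sum(x$var_explained[1:min(3, length(x$var_explained))])
  ))
  invisible(x)
}

#' Per-variable contributions to the principal components
#'
#' The contribution of variable j to component k is the squared loading as a
#' percentage of the component's total squared loadings,
#' \eqn{100 \, l_{jk}^2 / \sum_j l_{jk}^2}; contributions to each component
#' sum to 100. The combined PC1--PC2 contribution weights the two components
#' by their eigenvalues.
#'
#' @param pca A `dom_pca` object.
#' @return Tibble with `metric`, `contrib_pc1`, `contrib_pc2`,
#'   `combined_pc12` (all percent).
#' @export
pca_contributions <- function(pca) {
  stopifnot(inherits(pca, "dom_pca"))
  tibble::tibble(
    metric = rownames(pca$loadings),
    contrib_pc1 = pca$contributions[, 1],
    contrib_pc2 = pca$contributions[, 2],
    combined_pc12 = pca$combined_contrib_12
  )
}

#' Default analytical-family assignment for the composition metrics
#'
#' Wheel axes are chosen to be quasi-independent by drawing at most one
#' metric from each family of analytical principles: absorbance magnitude
#' (DOC-normalized absorption coefficients), absorbance spectral shape
#' (slopes and absorbance ratios), size-exclusion chromatography, and
#' elemental stoichiometry.
#'
#' @return Named character vector mapping metric name to family.
#' @export
default_family_map <- function() {
  c(
    suva = "absorbance_magnitude",
    sac350 = "absorbance_magnitude",
    sac420 = "absorbance_magnitude",
    s275_295 = "absorbance_shape",
    s350_400 = "absorbance_shape",
    sr = "absorbance_shape",
    e2e3 = "absorbance_shape",
    e4e6 = "absorbance_shape",
    bp = "size_exclusion",
    hsf = "size_exclusion",
    bb = "size_exclusion",
    lmwn = "size_exclusion",
    lmwa = "size_exclusion",
    hs_mw = "size_exclusion",
    doc_don = "stoichiometry"
  )
}

#' Select quasi-independent wheel axes from PCA contributions
#'
#' Within each analytical family, metrics whose combined PC1+PC2 contribution
#' falls below `threshold_pct` are screened out, and the highest-contributing
#' survivor is chosen (ties broken alphabetically, with a message). The
#' family constraint, not the threshold, governs inclusion: a family whose
#' members all fall below the threshold still contributes its best metric,
#' with a warning, so that an independent analytical principle (e.g.
#' stoichiometry) is represented even when it explains little ordination
#' variance. A family with no metric in the PCA at all is an error.
#'
#' @param pca A `dom_pca` object.
#' @param family_map Named character vector metric -> family; defaults to
#'   [default_family_map()]. Must cover every PCA column.
#' @param threshold_pct Contribution screening threshold, percent (default 2).
#' @param families Families to draw from, in axis order; defaults to the four
#'   canonical families.
#' @return A tibble of class `dom_axis_selection` with one row per chosen
#'   axis: `metric`, `family`, `combined_pc12`, `below_threshold`; attribute
#'   `threshold_pct`.
#' @export
select_axes <- function(pca, family_map = default_family_map(), threshold_pct = 2,
                        families = c(
                          "absorbance_magnitude", "absorbance_shape",
                          "size_exclusion", "stoichiometry"
                        )) {
  stopifnot(inherits(pca, "dom_pca"))
  uncovered <- setdiff(pca$columns, names(family_map))
  if (length(uncovered)) {
    abort(sprintf(
      "family_map does not cover column(s): %s", paste(uncovered, collapse = ", ")
    ))
  }
  contrib <- pca_contributions(pca)
  contrib$family <- unname(family_map[contrib$metric])

  empty <- setdiff(families, unique(contrib$family))
  if (length(empty)) {
    abort(sprintf(
      "No metric available for family/families: %s", paste(empty, collapse = ", ")
    ))
  }
  if (threshold_pct >= 100) {
    abort("threshold_pct must be below 100: no variable can survive the screen.")
  }

  picks <- purrr::map_dfr(families, function(fam) {
    cand <- contrib[contrib$family == fam, ]
    surv <- cand[cand$combined_pc12 >= threshold_pct, ]
    fell_back <- nrow(surv) == 0
    if (fell_back) {
      warn(sprintf(
        "Family '%s': every metric is below the %g%% contribution threshold; keeping its best metric anyway for independence.",
        fam, threshold_pct
      ))
      surv <- cand
    }
    best <- max(surv$combined_pc12)
    top <- sort(surv$metric[surv$combined_pc12 == best])
    if (length(top) > 1) {
      inform(sprintf(
        "Family '%s': contribution tie between %s; choosing '%s' (alphabetical).",
        fam, paste(top, collapse = ", "), top[1]
      ))
    }
    row <- surv[surv$metric == top[1], ]
    tibble::tibble(
      metric = row$metric, family = fam,
      combined_pc12 = row$combined_pc12, below_threshold = fell_back
    )
  })

  attr(picks, "threshold_pct") <- threshold_pct
  class(picks) <- c("dom_axis_selection", class(picks))
  picks
}

#' @rdname tidiers
#' @param matrix For `dom_pca`: which quantity to return, `"loadings"`
#'   (default, includes contributions), `"scores"`, or `"eigenvalues"`.
#' @exportS3Method generics::tidy
tidy.dom_pca <- function(x, matrix = c("loadings", "scores", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble::tibble(
      component = seq_along(x$eigenvalues),
      eigenvalue = x$eigenvalues,
      var_explained = x$var_explained,
      cum_var_explained = cumsum(x$var_explained)
    ))
  }
  if (matrix == "scores") {
    sc <- tibble::as_tibble(x$scores, .name_repair = "minimal")
    names(sc) <- paste0("PC", seq_len(ncol(sc)))
    sc$row <- seq_len(nrow(sc))
    return(tidyr::pivot_longer(sc, -"row",
      names_to = "component", values_to = "score"
    ))
  }
  ld <- tibble::as_tibble(x$loadings, rownames = "metric", .name_repair = "minimal")
  names(ld) <- c("metric", paste0("PC", seq_len(ncol(x$loadings))))
  long <- tidyr::pivot_longer(ld, -"metric", names_to = "component", values_to = "loading")
  long$contribution <- as.vector(t(x$contributions))
  long
}

#' Broom-style tidiers for domwheel objects
#'
#' `tidy()` returns the per-element detail of a fitted object as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x A `dom_pca` or `dom_axis_selection` object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.dom_pca <- function(x, ...) {
  tibble::tibble(
    n = x$n_complete,
    n_metrics = length(x$columns),
    pc1_var_pct = x$var_explained[1],
    pc2_var_pct = x$var_explained[2],
    pc12_var_pct = sum(x$var_explained[1:2]),
    pc123_var_pct = sum(x$var_explained[1:min(3, length(x$var_explained))])
  )
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.dom_axis_selection <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dom_axis_selection")
  out
}
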