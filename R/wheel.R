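# Canonical wheel layout: four axes at 90 degree spacing, oriented so the
# photolyzed end member elongates to the top-right (high S_275-295 axis).
DEFAULT_WHEEL_METRICS <- c("suva", "s275_295", "hsf", "doc_don")
DEFAULT_WHEEL_ANGLES <- c(suva = 135, s275_295 = 45, hsf = 315, doc_don = 225)

#' Fit wheel axes: per-metric min-max bounds over a reference dataset
#'
#' Each wheel axis is a composition metric normalized between the minimum and
#' maximum encountered for that metric within the reference dataset, so a
#' wheel value of 0 (1) means "the lowest (highest) value observed". The
#' returned axis set can be written with [write_bounds()] so later studies
#' can normalize against a fixed published range.
#'
#' @param metrics Metric table (rows = samples or site averages).
#' @param axis_metrics Metrics to use as axes, in wheel order; default the
#'   canonical quadruple SUVA, S_275-295, HSF, DOC:DON. Any k >= 3 works.
#' @param angles Axis angles in degrees (counter-clockwise from east); default
#'   90 degree spacing starting up-left for the canonical quadruple.
#' @return A tibble of class `dom_axes`: `metric`, `min`, `max`, `angle_deg`.
#' @export
fit_axes <- function(metrics, axis_metrics = DEFAULT_WHEEL_METRICS, angles = NULL) {
  if (length(axis_metrics) < 3) abort("A wheel needs at least 3 axes.")
  missing <- setdiff(axis_metrics, names(metrics))
  if (length(missing)) {
    abort(sprintf("Metric(s) not in table: %s", paste(missing, collapse = ", ")))
  }
  if (is.null(angles)) {
    angles <- if (identical(axis_metrics, DEFAULT_WHEEL_METRICS)) {
      unname(DEFAULT_WHEEL_ANGLES)
    } else {
      # 90/…  spacing starting at up-left, clockwise
      (135 - 90 * (seq_along(axis_metrics) - 1)) %% 360
    }
  }
  stopifnot(length(angles) == length(axis_metrics))

  bounds <- purrr::map_dfr(axis_metrics, function(m) {
    v <- metrics[[m]]
    v <- v[is.finite(v)]
    if (length(unique(v)) < 2) {
      abort(sprintf(
        "Axis metric '%s' needs at least 2 distinct finite values (constant or empty column).", m
      ))
    }
    tibble::tibble(metric = m, min = min(v), max = max(v))
  })
  bounds$angle_deg <- as.numeric(angles)
  class(bounds) <- c("dom_axes", class(bounds))
  bounds
}

#' Explicit axis bounds
#'
#' Builds a `dom_axes` object from stated min/max bounds (e.g. a published
#' range) instead of a reference dataset.
#'
#' @param metric Character vector of axis metrics, in wheel order.
#' @param min,max Numeric bounds per metric, `max > min`.
#' @param angles Axis angles in degrees; default 90 degree spacing.
#' @return A `dom_axes` tibble.
#' @export
manual_axes <- function(metric, min, max, angles = NULL) {
  stopifnot(length(metric) == length(min), length(min) == length(max))
  if (length(metric) < 3) abort("A wheel needs at least 3 axes.")
  if (any(max <= min)) {
    abort(sprintf(
      "max must exceed min for every axis (offender: %s).", metric[max <= min][1]
    ))
  }
  if (is.null(angles)) {
    angles <- if (identical(metric, DEFAULT_WHEEL_METRICS)) {
      unname(DEFAULT_WHEEL_ANGLES)
    } else {
      (135 - 90 * (seq_along(metric) - 1)) %% 360
    }
  }
  out <- tibble::tibble(
    metric = metric, min = as.numeric(min), max = as.numeric(max),
    angle_deg = as.numeric(angles)
  )
  class(out) <- c("dom_axes", class(out))
  out
}

#' Write / read axis bounds as CSV
#'
#' @param axes A `dom_axes` object.
#' @param path CSV path (`metric,min,max,angle_deg`).
#' @return `write_bounds()` returns `path` invisibly; `read_bounds()` the
#'   `dom_axes` tibble.
#' @export
write_bounds <- function(axes, path) {
  readr::write_csv(axes, path)
  invisible(path)
}

#' @rdname write_bounds
#' @export
read_bounds <- function(path) {
  if (!file.exists(path)) abort(sprintf("bounds file not found: %s", path))
  b <- readr::read_csv(path, col_types = "cddd", show_col_types = FALSE, progress = FALSE)
  manual_axes(b$metric, b$min, b$max, b$angle_deg)
}

#' Min-max normalize samples onto wheel axes
#'
#' Each sample's metric value is mapped to
#' \eqn{v = (x - \min) / (\max - \min)} against the axis bounds and clipped
#' into \[0, 1\]; clipping (a sample outside the reference range) is counted
#' and reported so wheels from new studies stay drawable against published
#' bounds. Samples missing any axis metric get no wheel and are reported.
#'
#' @param metrics Metric table with a `sample_id` column (a `site` /
#'   `hydro_setting` keyed table from [average_by_site()] also works; the
#'   first column is then used as the key).
#' @param axes A `dom_axes` object.
#' @return A tibble of class `dom_wheels`, long format: `sample_id`,
#'   `metric`, `angle_deg`, `value` in \[0,1\], `clipped`; attribute `axes`.
#' @export
normalize_wheels <- function(metrics, axes) {
  stopifnot(inherits(axes, "dom_axes"))
  key <- if ("sample_id" %in% names(metrics)) "sample_id" else names(metrics)[1]
  missing_ax <- setdiff(axes$metric, names(metrics))
  if (length(missing_ax)) {
    abort(sprintf("Metric(s) not in table: %s", paste(missing_ax, collapse = ", ")))
  }

  long <- metrics |>
    dplyr::select(sample_id = dplyr::all_of(key), dplyr::all_of(axes$metric)) |>
    dplyr::mutate(sample_id = as.character(.data$sample_id)) |>
    tidyr::pivot_longer(-"sample_id", names_to = "metric", values_to = "x") |>
    dplyr::inner_join(axes, by = "metric") |>
    dplyr::mutate(
      raw = (.data$x - .data$min) / (.data$max - .data$min),
      value = pmin(1, pmax(0, .data$raw)),
      clipped = is.finite(.data$raw) & (.data$raw < 0 | .data$raw > 1)
    )

  incomplete <- unique(long$sample_id[!is.finite(long$x)])
  if (length(incomplete)) {
    inform(sprintf(
      "%d sample(s) dropped (missing at least one axis metric): %s%s",
      length(incomplete), paste(head(incomplete, 5), collapse = ", "),
      if (length(incomplete) > 5) ", ..." else ""
    ))
    long <- long[!long$sample_id %in% incomplete, ]
  }
  n_clip <- sum(long$clipped)
  if (n_clip) {
    warn(sprintf("%d axis value(s) outside the reference range were clipped to [0, 1].", n_clip))
  }

  # preserve axis order within each sample
  long <- long |>
    dplyr::mutate(metric = factor(.data$metric, levels = axes$metric)) |>
    dplyr::arrange(.data$sample_id, .data$metric) |>
    dplyr::mutate(metric = as.character(.data$metric)) |>
    dplyr::select("sample_id", "metric", "angle_deg", "value", "clipped")

  attr(long, "axes") <- axes
  class(long) <- c("dom_wheels", class(long))
  long
}

wheels_matrix <- function(wheels) {
  axes <- attr(wheels, "axes")
  wide <- tidyr::pivot_wider(
    wheels[, c("sample_id", "metric", "value")],
    names_from = "metric", values_from = "value"
  )
  m <- as.matrix(wide[, axes$metric, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}

#' Wheel polygon vertices
#'
#' Places vertex i at \eqn{(r v_i \cos\theta_i, r v_i \sin\theta_i)}; the
#' polygon closes in axis order.
#'
#' @param wheels A `dom_wheels` tibble.
#' @param radius Wheel radius (the distance of a value of 1 from the centre).
#' @return Tibble `sample_id`, `metric`, `x`, `y`, vertices in axis order.
#' @export
wheel_polygon <- function(wheels, radius = 1) {
  stopifnot(inherits(wheels, "dom_wheels"))
  dplyr::mutate(
    tibble::as_tibble(wheels)[, c("sample_id", "metric", "angle_deg", "value")],
    x = radius * .data$value * cos(.data$angle_deg * pi / 180),
    y = radius * .data$value * sin(.data$angle_deg * pi / 180)
  )[, c("sample_id", "metric", "x", "y")]
}

#' Wheel polygon area
#'
#' Shoelace area of each sample's polygon at unit radius; for four orthogonal
#' axes this equals \eqn{\tfrac{1}{2}\sum_i v_i v_{i+1}} (cyclic). An
#' all-ones wheel has area 2.
#'
#' @param wheels A `dom_wheels` tibble.
#' @return Tibble `sample_id`, `area`.
#' @export
wheel_area <- function(wheels) {
  verts <- wheel_polygon(wheels, radius = 1)
  verts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(area = shoelace(.data$x, .data$y), .groups = "drop")
}

shoelace <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Distance between two wheels
#'
#' Euclidean distance between the normalized axis-value vectors; zero iff the
#' wheels are identical. Both wheels must share the same axis set.
#'
#' @param wheel_a,wheel_b Single-sample `dom_wheels` tibbles (or numeric
#'   vectors of normalized values in matching axis order).
#' @return Non-negative scalar distance.
#' @export
wheel_distance <- function(wheel_a, wheel_b) {
  va <- wheel_values(wheel_a)
  vb <- wheel_values(wheel_b)
  if (!is.null(names(va)) && !is.null(names(vb)) && !identical(names(va), names(vb))) {
    abort("Wheels use different axis sets; cannot compare.")
  }
  if (length(va) != length(vb)) abort("Wheels have different numbers of axes.")
  sqrt(sum((va - vb)^2))
}

wheel_values <- function(w) {
  if (is.numeric(w)) return(w)
  stopifnot(inherits(w, "dom_wheels") || is.data.frame(w))
  if (length(unique(w$sample_id)) != 1) {
    abort("Expected a single-sample wheel; filter to one sample_id first.")
  }
  stats::setNames(w$value, w$metric)
}

#' End-member template wheels
#'
#' Qualitative end-member compositions expressed on the normalized axes, with
#' levels low/mid/high anchored at 0.15 / 0.5 / 0.85 (package conventions for
#' drawing and classification, not measured values). The `groundwater`
#' template is high SUVA, low S_275-295, high HSF and, by default, high
#' DOC:DON (the configuration observed for groundwater across the dataset);
#' `variant = "caption"` switches DOC:DON to low, an alternative published
#' characterization of the same end member. `photolyzed` is high S_275-295
#' with the other three axes low (the kite shape). The remaining templates
#' are process/source sketches: `microbially_degraded` (raised SUVA, lowered
#' DOC:DON, S and HSF untouched), `terrestrial_leachate` (fresh high-HSF,
#' high-DOC:DON material) and `aquatic_production` (autochthonous,
#' protein-rich, low-HSF DOM).
#'
#' @param variant `"results"` (default) or `"caption"`, controlling the
#'   groundwater template's DOC:DON level.
#' @param metrics Axis metrics, in wheel order; templates are defined for the
#'   canonical quadruple.
#' @param which Template names to return; default all five. Classification
#'   defaults to the two dominant end members only (see [classify_wheels()]).
#' @return A tibble `template`, `metric`, `level`, `value`.
#' @export
end_member_templates <- function(variant = c("results", "caption"),
                                 metrics = DEFAULT_WHEEL_METRICS,
                                 which = NULL) {
  variant <- match.arg(variant)
  anchors <- c(low = 0.15, mid = 0.5, high = 0.85)
  gw_docdon <- if (variant == "results") "high" else "low"
  levels <- list(
    groundwater = c(suva = "high", s275_295 = "low", hsf = "high", doc_don = gw_docdon),
    photolyzed = c(suva = "low", s275_295 = "high", hsf = "low", doc_don = "low"),
    microbially_degraded = c(suva = "high", s275_295 = "mid", hsf = "mid", doc_don = "low"),
    terrestrial_leachate = c(suva = "mid", s275_295 = "low", hsf = "high", doc_don = "high"),
    aquatic_production = c(suva = "low", s275_295 = "mid", hsf = "low", doc_don = "low")
  )
  if (!is.null(which)) {
    unknown <- setdiff(which, names(levels))
    if (length(unknown)) {
      abort(sprintf("Unknown template(s): %s", paste(unknown, collapse = ", ")))
    }
    levels <- levels[which]
  }
  purrr::map_dfr(names(levels), function(tmpl) {
    lv <- levels[[tmpl]][metrics]
    tibble::tibble(
      template = tmpl, metric = metrics,
      level = unname(lv), value = unname(anchors[lv])
    )
  })
}

#' Classify wheels against end-member templates
#'
#' Assigns each sample the nearest template by Euclidean distance in
#' normalized axis space. Samples farther than `cutoff` from every template
#' are labelled `"intermediate"` (they sit between end members). Exact ties
#' go to the earlier template in `templates` order, with a message.
#'
#' By default samples are classified against the two dominant end-member
#' shapes observed in natural datasets -- groundwater-sourced DOM and
#' photolyzed DOM -- between which surface-water samples form a continuum.
#' The process-sketch templates (microbial, leachate, autochthonous) overlap
#' these two on most axes and are for overlay/interpretation; include them
#' explicitly via `end_member_templates()` if wanted.
#'
#' @param wheels A `dom_wheels` tibble.
#' @param templates Template tibble from [end_member_templates()] (or the
#'   same shape); axis metrics must match the wheels'.
#' @param cutoff Distance beyond which a sample is called intermediate
#'   (default 0.6).
#' @return Tibble `sample_id`, `class`, `distance` (distance to the nearest
#'   template even when intermediate).
#' @export
classify_wheels <- function(wheels,
                            templates = end_member_templates(
                              which = c("groundwater", "photolyzed")
                            ),
                            cutoff = 0.6) {
  stopifnot(inherits(wheels, "dom_wheels"))
  axes <- attr(wheels, "axes")
  tnames <- unique(templates$template)
  if (!length(tnames)) abort("No templates supplied.")
  tm <- vapply(tnames, function(tn) {
    row <- templates[templates$template == tn, ]
    v <- row$value[match(axes$metric, row$metric)]
    if (any(is.na(v))) {
      abort(sprintf("Template '%s' does not cover axis metric(s) of these wheels.", tn))
    }
    v
  }, numeric(nrow(axes)))

  m <- wheels_matrix(wheels)
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    d <- sqrt(colSums((tm - m[i, ])^2))
    best <- min(d)
    hit <- tnames[d == best]
    if (length(hit) > 1) {
      inform(sprintf(
        "Sample '%s': equidistant from %s; assigning '%s' (template order).",
        rownames(m)[i], paste(hit, collapse = ", "), hit[1]
      ))
    }
    tibble::tibble(
      sample_id = rownames(m)[i],
      class = if (best > cutoff) "intermediate" else hit[1],
      distance = best
    )
  })
  res
}

#' Expected direction of change under a degradation process
#'
#' Annotates each canonical wheel axis with the expected sign of change for a
#' given degradation process. Photolysis raises S_275-295 and generally
#' lowers SUVA, HSF and DOC:DON (all four axes respond); microbial
#' degradation raises SUVA and lowers DOC:DON while leaving S_275-295 and
#' HSF essentially unchanged (two axes respond). The vector is an annotation
#' for interpreting observed wheel shifts; it is never applied to data.
#'
#' @param process `"photolysis"` or `"microbial"`.
#' @return Tibble `metric`, `direction` (+1, 0, -1), `label`.
#' @export
degradation_shift <- function(process) {
  shifts <- list(
    photolysis = c(suva = -1, s275_295 = 1, hsf = -1, doc_don = -1),
    microbial = c(suva = 1, s275_295 = 0, hsf = 0, doc_don = -1)
  )
  if (!is.character(process) || length(process) != 1 || !process %in% names(shifts)) {
    abort(sprintf(
      "Unknown process '%s'; must be one of: %s.",
      as.character(process)[1], paste(names(shifts), collapse = ", ")
    ))
  }
  s <- shifts[[process]]
  tibble::tibble(
    metric = names(s),
    direction = unname(s),
    label = c("-1" = "decrease", "0" = "no change", "1" = "increase")[as.character(s)]
  )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.dom_wheels <- function(x, ...) {
  ar <- wheel_area(x)
  tibble::tibble(
    n_wheels = length(unique(x$sample_id)),
    n_axes = nrow(attr(x, "axes")),
    n_clipped = sum(x$clipped),
    mean_area = mean(ar$area)
  )
}
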