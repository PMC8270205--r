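# Deterministic SVG output: fixed-precision coordinates, no timestamps, no
# generated ids, stable element order, so identical inputs give identical
# bytes (diffable in version control and in tests).

SITE_PALETTE <- c(
  "#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e", "#e6ab02",
  "#a6761d", "#666666", "#1f78b4", "#b2df8a", "#fb9a99", "#cab2d6"
)

fmt <- function(x) sprintf("%.2f", x)

svg_polygon <- function(verts, cx, cy, radius, stroke, fill, width, cls) {
  pts <- paste(
    fmt(cx + radius * verts$x), fmt(cy - radius * verts$y),
    sep = ",", collapse = " "
  )
  sprintf(
    '<polygon class="%s" points="%s" fill="%s" fill-opacity="0.25" stroke="%s" stroke-width="%s"/>',
    cls, pts, fill, stroke, fmt(width)
  )
}

svg_axes <- function(axes, cx, cy, radius, labels) {
  out <- character(0)
  for (i in seq_len(nrow(axes))) {
    th <- axes$angle_deg[i] * pi / 180
    x2 <- cx + radius * cos(th)
    y2 <- cy - radius * sin(th)
    out <- c(out, sprintf(
      '<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#bbbbbb" stroke-width="1"/>',
      fmt(cx), fmt(cy), fmt(x2), fmt(y2)
    ))
    if (labels) {
      lx <- cx + 1.18 * radius * cos(th)
      ly <- cy - 1.18 * radius * sin(th)
      out <- c(out, sprintf(
        '<text class="axis-label" x="%s" y="%s" font-size="10" text-anchor="middle" dominant-baseline="middle">%s</text>',
        fmt(lx), fmt(ly), axes$metric[i]
      ))
    }
  }
  out
}

wheel_panel_svg <- function(wheels, axes, cx, cy, radius, colors, widths, classes,
                            show_labels = TRUE, template_wheels = NULL) {
  verts <- wheel_polygon(wheels, radius = 1)
  ids <- unique(wheels$sample_id)
  body <- svg_axes(axes, cx, cy, radius, labels = show_labels)
  if (!is.null(template_wheels)) {
    tverts <- wheel_polygon(template_wheels, radius = 1)
    for (tn in unique(template_wheels$sample_id)) {
      body <- c(body, svg_polygon(
        tverts[tverts$sample_id == tn, ], cx, cy, radius,
        stroke = "#000000", fill = "none", width = 1, cls = paste0("template-", tn)
      ))
    }
  }
  for (id in ids) {
    body <- c(body, svg_polygon(
      verts[verts$sample_id == id, ], cx, cy, radius,
      stroke = colors[[id]], fill = colors[[id]],
      width = widths[[id]], cls = classes[[id]]
    ))
  }
  body
}

#' Render Composition Wheels to a deterministic SVG (or PNG)
#'
#' Draws every wheel in `wheels` overlaid in a single panel: grey axis
#' spokes, one closed polygon per sample. SVG output is byte-for-byte
#' reproducible for identical inputs; PNG goes through ggplot2 and the local
#' raster device and is a convenience only.
#'
#' @param wheels A `dom_wheels` tibble.
#' @param path Output file path.
#' @param radius_px Wheel radius in pixels (default 100).
#' @param show_labels Draw axis metric labels (default `TRUE`).
#' @param overlay_templates Optional template tibble (see
#'   [end_member_templates()]) drawn as unfilled black outlines.
#' @param colors Optional named vector sample_id -> color; defaults to a
#'   fixed qualitative palette in sample order.
#' @param highlight Character vector of sample ids drawn with a heavier
#'   stroke (end-member highlighting).
#' @param format `"svg"` (default) or `"png"`.
#' @return `path`, invisibly.
#' @export
render_wheel <- function(wheels, path, radius_px = 100, show_labels = TRUE,
                         overlay_templates = NULL, colors = NULL,
                         highlight = character(0), format = c("svg", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(wheels, "dom_wheels"))
  if (format == "png") {
    p <- ggplot2::autoplot(wheels)
    grDevices::png(path, width = 4 * radius_px, height = 4 * radius_px, res = 96)
    on.exit(grDevices::dev.off())
    print(p)
    return(invisible(path))
  }

  axes <- attr(wheels, "axes")
  ids <- unique(wheels$sample_id)
  if (is.null(colors)) {
    colors <- stats::setNames(rep_len(SITE_PALETTE, length(ids)), ids)
  }
  widths <- stats::setNames(ifelse(ids %in% highlight, 3, 1.2), ids)
  classes <- stats::setNames(
    ifelse(ids %in% highlight, "wheel highlighted", "wheel"), ids
  )

  margin <- if (show_labels) 40 else 10
  side <- 2 * radius_px + 2 * margin
  tmpl <- template_as_wheels(overlay_templates, axes)
  body <- wheel_panel_svg(
    wheels, axes, side / 2, side / 2, radius_px,
    as.list(colors), as.list(widths), as.list(classes),
    show_labels = show_labels, template_wheels = tmpl
  )
  write_svg_file(body, side, side, path)
}

template_as_wheels <- function(templates, axes) {
  if (is.null(templates)) return(NULL)
  w <- templates |>
    dplyr::select(sample_id = "template", "metric", "value") |>
    dplyr::inner_join(axes[, c("metric", "angle_deg")], by = "metric") |>
    dplyr::mutate(clipped = FALSE)
  w <- w[order(
    w$sample_id,
    match(w$metric, axes$metric)
  ), c("sample_id", "metric", "angle_deg", "value", "clipped")]
  attr(w, "axes") <- axes
  class(w) <- c("dom_wheels", class(w))
  w
}

write_svg_file <- function(body, width, height, path) {
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
      round(width), round(height), round(width), round(height)
    ),
    body,
    "</svg>"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Render a site-by-setting grid of Composition Wheels
#'
#' One panel per (site, hydro_setting) combination present in the metadata,
#' samples from the same combination overlaid within their panel; color
#' encodes the geographic site, the panel the hydrologic setting. Empty
#' combinations are omitted. Deterministic SVG, as for [render_wheel()].
#'
#' @param wheels A `dom_wheels` tibble.
#' @param meta Metadata tibble (`sample_id`, `site`, `hydro_setting`).
#' @param path Output SVG path.
#' @param radius_px Per-panel wheel radius in pixels.
#' @param highlight Sample ids drawn with a heavier stroke.
#' @param overlay_templates Optional template tibble overlaid in each panel.
#' @return `path`, invisibly.
#' @export
render_facets <- function(wheels, meta, path, radius_px = 70,
                          highlight = character(0), overlay_templates = NULL) {
  stopifnot(inherits(wheels, "dom_wheels"))
  axes <- attr(wheels, "axes")
  joined <- dplyr::inner_join(
    tibble::as_tibble(wheels),
    dplyr::select(meta, "sample_id", "site", "hydro_setting"),
    by = "sample_id"
  )
  panels <- dplyr::distinct(joined, .data$site, .data$hydro_setting) |>
    dplyr::arrange(.data$site, .data$hydro_setting)
  sites <- sort(unique(panels$site))
  settings <- sort(unique(panels$hydro_setting))
  site_col <- stats::setNames(rep_len(SITE_PALETTE, length(sites)), sites)

  margin <- 45
  cell <- 2 * radius_px + margin
  width <- length(settings) * cell + margin
  height <- length(sites) * cell + margin
  tmpl <- template_as_wheels(overlay_templates, axes)

  body <- character(0)
  for (pi in seq_len(nrow(panels))) {
    st <- panels$site[pi]
    hs <- panels$hydro_setting[pi]
    col_i <- match(hs, settings)
    row_i <- match(st, sites)
    cx <- margin / 2 + (col_i - 0.5) * cell + margin / 2
    cy <- margin / 2 + (row_i - 0.5) * cell + margin / 2
    sub_ids <- unique(joined$sample_id[joined$site == st & joined$hydro_setting == hs])
    sub <- wheels[wheels$sample_id %in% sub_ids, ]
    attr(sub, "axes") <- axes
    class(sub) <- c("dom_wheels", class(tibble::as_tibble(sub)))
    colors <- stats::setNames(rep(site_col[[st]], length(sub_ids)), sub_ids)
    widths <- stats::setNames(ifelse(sub_ids %in% highlight, 3, 1), sub_ids)
    classes <- stats::setNames(
      ifelse(sub_ids %in% highlight, "wheel highlighted", "wheel"), sub_ids
    )
    body <- c(
      body,
      sprintf('<g class="panel" data-site="%s" data-setting="%s">', st, hs),
      sprintf(
        '<text x="%s" y="%s" font-size="11" text-anchor="middle">%s / %s</text>',
        fmt(cx), fmt(cy - radius_px - 12), st, hs
      ),
      wheel_panel_svg(
        sub, axes, cx, cy, radius_px,
        as.list(colors), as.list(widths), as.list(classes),
        show_labels = FALSE, template_wheels = tmpl
      ),
      "</g>"
    )
  }
  write_svg_file(body, width, height, path)
}

#' Plot Composition Wheels with ggplot2
#'
#' Radar-style polygon plot of the normalized wheels; with `meta`, panels are
#' faceted by site and hydrologic setting as in the standard small-multiples
#' layout.
#'
#' @param object A `dom_wheels` tibble.
#' @param meta Optional metadata for faceting (`sample_id`, `site`,
#'   `hydro_setting`) and site coloring.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dom_wheels <- function(object, meta = NULL, ...) {
  axes <- attr(object, "axes")
  verts <- wheel_polygon(object, radius = 1)
  spokes <- tibble::tibble(
    metric = axes$metric,
    x = cos(axes$angle_deg * pi / 180),
    y = sin(axes$angle_deg * pi / 180)
  )
  p <- ggplot2::ggplot(verts, ggplot2::aes(x = .data$x, y = .data$y, group = .data$sample_id))
  if (!is.null(meta)) {
    verts <- dplyr::inner_join(
      verts, dplyr::select(meta, "sample_id", "site", "hydro_setting"),
      by = "sample_id"
    )
    p <- ggplot2::ggplot(verts, ggplot2::aes(
      x = .data$x, y = .data$y, group = .data$sample_id, color = .data$site,
      fill = .data$site
    )) +
      ggplot2::facet_grid(site ~ hydro_setting)
  }
  p +
    ggplot2::geom_segment(
      data = spokes, inherit.aes = FALSE,
      ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
      color = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_text(
      data = spokes, inherit.aes = FALSE,
      ggplot2::aes(x = 1.25 * .data$x, y = 1.25 * .data$y, label = .data$metric),
      size = 3
    ) +
    ggplot2::geom_polygon(alpha = 0.25, linewidth = 0.5) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "bottom")
}

#' @rdname autoplot.dom_wheels
#' @param wheels A `dom_wheels` tibble.
#' @export
plot_wheels <- function(wheels, meta = NULL, ...) autoplot.dom_wheels(wheels, meta = meta, ...)

#' Scree / contribution plot for a composition PCA
#'
#' Bar chart of each metric's combined contribution to PC1+PC2 with the
#' screening threshold drawn as a dashed line.
#'
#' @param pca A `dom_pca` object.
#' @param threshold_pct Threshold line, percent (default 2).
#' @return A ggplot object.
#' @export
plot_contributions <- function(pca, threshold_pct = 2) {
  d <- pca_contributions(pca)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$metric, -.data$combined_pc12),
    y = .data$combined_pc12
  )) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::geom_hline(yintercept = threshold_pct, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Contribution to PC1+PC2 (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
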