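# Visual outputs. Every figure has a machine-readable twin (a data frame,
# optionally written as CSV) holding exactly the plotted values; tests
# assert on twins, never on pixels.

#' MRC graph: NDUFB8 vs MTCO1 Z-scores per cell
#'
#' Scatter of `z_ndufb8` (y) against `z_mtco1` (x), one spot per cell with
#' radius proportional to the square root of cell area (so spot area is
#' proportional to cell area), and reference lines at the +/-3 SD
#' deficiency thresholds. With `density = TRUE` a 2-D density layer
#' replaces the spots (per group when a `group` column is present).
#'
#' @param z_records classified records; rows with non-finite z are
#'   dropped.
#' @param out_png optional figure path (device chosen by extension:
#'   `.png` or `.pdf`).
#' @param twin_csv optional path for the plotted-point table.
#' @param ref SD threshold drawn as reference lines.
#' @param size_scale multiplier applied to `sqrt(area_px)` for spot radius.
#' @param density draw a density variant instead of spots.
#' @return Invisibly, a list with `points` (the twin: `cell_id`, `x`, `y`,
#'   `size`, plus `group` if present), `figure` (ggplot object) and `file`.
#' @export
mrc_graph <- function(z_records, out_png = NULL, twin_csv = NULL,
                      ref = 3, size_scale = 0.1, density = FALSE) {
  d <- z_records[is.finite(z_records$z_ndufb8) &
                   is.finite(z_records$z_mtco1), , drop = FALSE]
  if (nrow(d) == 0) stop("no cells with finite Z-scores to plot")
  pts <- data.frame(cell_id = d$cell_id, x = d$z_mtco1, y = d$z_ndufb8,
                    size = size_scale * sqrt(d$area_px),
                    stringsAsFactors = FALSE)
  if ("group" %in% names(d)) pts$group <- d$group
  fig <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = c(-ref, ref), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(-ref, ref), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "MTCO1 Z-score", y = "NDUFB8 Z-score") +
    ggplot2::theme_classic()
  if (density) {
    fig <- fig + ggplot2::stat_density_2d(
      ggplot2::aes(fill = ggplot2::after_stat(level)),
      geom = "polygon", alpha = 0.4)
    if ("group" %in% names(pts))
      fig <- fig + ggplot2::facet_wrap(~group)
  } else {
    fig <- fig + ggplot2::geom_point(
      ggplot2::aes(size = .data$size),
      alpha = 0.5, colour = "#2166AC") +
      ggplot2::scale_size_identity()
  }
  if (!is.null(twin_csv)) write.csv(pts, twin_csv, row.names = FALSE)
  if (!is.null(out_png)) save_figure(fig, out_png)
  invisible(list(points = pts, figure = fig, file = out_png))
}

#' Diverging colour for a Z-score
#'
#' Blue (low) through neutral white to red (high), clipped at
#' `+/- clip`.
#' @param z numeric Z-scores.
#' @param clip symmetric clipping limit in SD units.
#' @return Character vector of hex colours.
#' @export
z_colour <- function(z, clip = 6) {
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(255)
  zc <- pmin(pmax(z, -clip), clip)
  pal[1L + round((zc + clip) / (2 * clip) * 254)]
}

#' Pseudo-colour Z-score image
#'
#' Fills each cell footprint in the label mask with a diverging colour
#' mapped from that cell's Z-score for the chosen marker (blue = low
#' abundance, red = high), clipped at `+/- clip` SD. Background keeps a
#' fixed neutral colour; mask labels that have no matching record are
#' filled with `missing_colour` and raise a warning.
#'
#' @param mask H x W integer label mask.
#' @param z_records classified records whose `label` (or `cell_id`) column
#'   joins to mask labels.
#' @param marker `"ndufb8"`, `"mtco1"` or `"tomm20"`.
#' @param out_png optional figure path.
#' @param twin_csv optional path for the per-cell colour table.
#' @param clip clipping limit (SD units).
#' @param background,missing_colour hex colours.
#' @return Invisibly, a list with `colour_table` (twin: `label`, `z`,
#'   `z_clipped`, `colour`), `raster` (H x W hex matrix) and `file`.
#' @export
pseudo_image <- function(mask, z_records, marker = "ndufb8",
                         out_png = NULL, twin_csv = NULL, clip = 6,
                         background = "#1A1A1A",
                         missing_colour = "#888888") {
  zcol <- paste0("z_", marker)
  if (!zcol %in% names(z_records)) stop("unknown marker: ", marker)
  labs <- sort(unique(mask[mask > 0]))
  m <- match(labs, z_records$label)
  z <- z_records[[zcol]][m]
  missing <- is.na(m) | !is.finite(z)
  if (any(missing))
    warning(sum(missing), " mask label(s) missing from z_records")
  colr <- ifelse(missing, missing_colour, z_colour(z, clip))
  twin <- data.frame(label = labs, z = z,
                     z_clipped = pmin(pmax(z, -clip), clip),
                     colour = colr, stringsAsFactors = FALSE)
  raster <- matrix(background, nrow(mask), ncol(mask))
  lut <- character(max(labs))
  lut[labs] <- colr
  sel <- mask > 0
  raster[sel] <- lut[mask[sel]]
  if (!is.null(twin_csv)) write.csv(twin, twin_csv, row.names = FALSE)
  if (!is.null(out_png)) {
    open_device(out_png, width = ncol(mask), height = nrow(mask))
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::rasterImage(grDevices::as.raster(raster), 0, 0, 1, 1,
                          interpolate = FALSE)
    grDevices::dev.off()
  }
  invisible(list(colour_table = twin, raster = raster, file = out_png))
}

#' ROI mean Z-score heatmap
#'
#' Matrix of mean Z-score per ROI (rows) and marker (columns), optionally
#' sorted by one marker's values and/or by a grouping column; the matrix is
#' the figure's twin.
#'
#' @param roi_means output of [roi_mean_z()].
#' @param markers markers to include, in column order.
#' @param sort_by marker whose mean z orders the rows (ascending), or
#'   `NULL` to keep input order.
#' @param sort_groups optional grouping column (e.g. `"group"`) applied
#'   before the marker sort.
#' @param out_png optional figure path.
#' @param twin_csv optional path for the matrix table.
#' @return Invisibly, a list with `matrix` (twin data frame: `roi_id`,
#'   grouping columns, one `mean_z_<marker>` column each), `figure` and
#'   `file`.
#' @export
roi_heatmap <- function(roi_means,
                        markers = c("ndufb8", "mtco1", "tomm20"),
                        sort_by = NULL, sort_groups = NULL,
                        out_png = NULL, twin_csv = NULL) {
  cols <- paste0("mean_z_", markers)
  if (!all(cols %in% names(roi_means)))
    stop("requested marker absent from ROI summaries: ",
         paste(markers[!cols %in% names(roi_means)], collapse = ", "))
  d <- roi_means
  ord <- seq_len(nrow(d))
  if (!is.null(sort_groups)) ord <- order(d[[sort_groups]])
  if (!is.null(sort_by)) {
    sc <- paste0("mean_z_", sort_by)
    if (!sc %in% names(d)) stop("requested marker absent: ", sort_by)
    ord <- if (is.null(sort_groups)) order(d[[sc]]) else
      order(d[[sort_groups]], d[[sc]])
  }
  d <- d[ord, , drop = FALSE]
  keep <- c("roi_id", intersect(c("group", "patient_id", "region"),
                                names(d)), cols)
  twin <- d[, keep, drop = FALSE]
  rownames(twin) <- NULL
  long <- do.call(rbind, lapply(seq_along(markers), function(i)
    data.frame(roi_id = factor(d$roi_id, levels = rev(d$roi_id)),
               marker = markers[i], mean_z = d[[cols[i]]])))
  fig <- ggplot2::ggplot(long, ggplot2::aes(x = .data$marker,
                                            y = .data$roi_id,
                                            fill = .data$mean_z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "#F7F7F7",
                                  high = "#B2182B", limits = c(-6, 6),
                                  oob = scales_squish) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean Z") +
    ggplot2::theme_minimal()
  if (!is.null(twin_csv)) write.csv(twin, twin_csv, row.names = FALSE)
  if (!is.null(out_png)) save_figure(fig, out_png)
  invisible(list(matrix = twin, figure = fig, file = out_png))
}

# clamp out-of-range values into the fill limits (scales::squish without
# the dependency)
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  force(range)
  finite <- if (only.finite) is.finite(x) else TRUE
  x[finite & x < range[1]] <- range[1]
  x[finite & x > range[2]] <- range[2]
  x
}

open_device <- function(path, width = 800, height = 600) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdf") {
    grDevices::pdf(path, width = width / 96, height = height / 96)
  } else if (capabilities("png")) {
    grDevices::png(path, width = width, height = height)
  } else {
    grDevices::pdf(sub("\\.png$", ".pdf", path), width = width / 96,
                   height = height / 96)
  }
}

save_figure <- function(fig, path, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(path))
  dev <- if (ext == "pdf" || !capabilities("png")) "pdf" else "png"
  suppressMessages(ggplot2::ggsave(path, fig, width = width,
                                   height = height, dpi = 120,
                                   device = dev))
  invisible(path)
}
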