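# End-to-end pipeline: simulate -> build library -> render -> unmix ->
# segment -> quantify -> score -> compare -> report.

#' Run the full synthetic-to-report pipeline
#'
#' Simulates a cohort from `config`, renders each ROI as a multispectral
#' cube, rebuilds the spectral library from simulated single-stain
#' reference cubes, unmixes every ROI, segments and quantifies cells (or
#' reuses the ground-truth masks), fits the control model on young-benign
#' epithelial cells, scores and classifies every cell, computes cohort
#' summaries and comparisons, and writes the three figure types with their
#' machine-readable twins.
#'
#' @param config a [sim_config()], or the path to its YAML serialisation.
#' @param out_dir output directory (created if needed).
#' @param segmentation `"watershed"` to segment the unmixed images, or
#'   `"ground_truth"` to reuse the simulator's masks (exercises the
#'   statistics independent of segmentation quality).
#' @param seg_params a [segment_params()].
#' @param min_control_cells minimum usable control cells for the model fit.
#' @param write_tiffs also write each ROI's cube and mask as TIFF (off by
#'   default; cubes are large).
#' @param verbose print progress to stderr.
#' @return Invisibly, a list with `cells`, `model`, `z_records`,
#'   `summaries` (by group / patient / ROI), `roi_means`, `comparisons`,
#'   `figures` (paths) and `out_dir`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("oxphos_"),
                         segmentation = c("watershed", "ground_truth"),
                         seg_params = segment_params(),
                         min_control_cells = 100L,
                         write_tiffs = FALSE, verbose = TRUE) {
  segmentation <- match.arg(segmentation)
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulating cell population ...")
  pop <- simulate_cell_population(config)
  true_lib <- make_spectral_library()

  say("building spectral library from single-stain references ...")
  lib <- build_library_from_reference_cubes(true_lib, config)
  write_spectral_library(lib, file.path(out_dir, "spectral_library.yaml"))

  rois <- unique(pop$cells$roi_id)
  say("rendering + unmixing + quantifying %d ROIs ...", length(rois))
  cell_tabs <- vector("list", length(rois))
  first_roi <- NULL
  for (i in seq_along(rois)) {
    roi <- rois[i]
    roi_cells <- pop$cells[pop$cells$roi_id == roi, , drop = FALSE]
    tc <- render_tissue_cube(roi_cells, true_lib, config)
    comp <- unmix_cube(tc, lib)
    mask <- if (segmentation == "watershed")
      segment_cells(comp, seg_params) else tc$mask
    tissue <- classify_tissue(comp, mask)
    ann <- roi_cells[1, c("patient_id", "group", "roi_id", "region")]
    cell_tabs[[i]] <- quantify_cells(comp, mask, ann, tissue)
    if (write_tiffs) {
      write_cube_tiff(tc, file.path(out_dir, paste0(roi, "_cube.tif")))
      write_mask_tiff(mask, file.path(out_dir, paste0(roi, "_mask.tif")))
    }
    if (is.null(first_roi))
      first_roi <- list(roi = roi, mask = mask)
  }
  cells <- do.call(rbind, cell_tabs)
  rownames(cells) <- NULL
  write_cell_table(cells, file.path(out_dir, "cells.csv"))

  say("fitting control model on %s epithelial cells ...", config$groups[1])
  model <- fit_control_model(cells, min_n = min_control_cells,
                             control_group = "young_benign")
  write_control_model(model, file.path(out_dir, "control_model.yaml"))

  z <- classify_cells(compute_zscores(cells, model))
  write.csv(z, file.path(out_dir, "zscores.csv"), row.names = FALSE)

  say("cohort summaries and comparisons ...")
  summaries <- list(
    by_group = category_proportions(z, "group"),
    by_patient = category_proportions(z, c("group", "patient_id")),
    by_roi = category_proportions(z, c("group", "patient_id", "roi_id")))
  for (nm in names(summaries))
    write.csv(summaries[[nm]],
              file.path(out_dir, paste0("summary_", nm, ".csv")),
              row.names = FALSE)
  roi_means <- roi_mean_z(z)
  write.csv(roi_means, file.path(out_dir, "roi_mean_z.csv"),
            row.names = FALSE)

  comparisons <- pipeline_comparisons(z, roi_means, config)
  write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
            row.names = FALSE)

  say("figures ...")
  figures <- list()
  figures$mrc <- mrc_graph(
    z[!z$invalid & !is.na(z$tissue_class) &
        z$tissue_class == "epithelial", , drop = FALSE],
    out_png = file.path(out_dir, "mrc_graph.png"),
    twin_csv = file.path(out_dir, "mrc_graph_points.csv"))$file
  z_first <- z[z$roi_id == first_roi$roi, , drop = FALSE]
  figures$pseudo <- pseudo_image(
    first_roi$mask, z_first, marker = "ndufb8",
    out_png = file.path(out_dir, "pseudo_ndufb8.png"),
    twin_csv = file.path(out_dir, "pseudo_ndufb8_colours.csv"))$file
  figures$heatmap <- roi_heatmap(
    roi_means, sort_by = "ndufb8", sort_groups = "group",
    out_png = file.path(out_dir, "roi_heatmap.png"),
    twin_csv = file.path(out_dir, "roi_heatmap_matrix.csv"))$file

  say("done: %s", out_dir)
  invisible(list(cells = cells, model = model, z_records = z,
                 summaries = summaries, roi_means = roi_means,
                 comparisons = comparisons, figures = figures,
                 out_dir = out_dir))
}

# Single-stain reference cubes rendered from the true library (uniform
# abundance patch per fluorophore, noiseless) plus an
# autofluorescence-only cube; used to rebuild the working library the way
# an acquisition protocol would.
build_library_from_reference_cubes <- function(true_lib, config,
                                               size = 32L, level = 5) {
  B <- length(true_lib$wavelengths)
  af_level <- config$image$af_level
  af_cube <- array(rep(af_level * true_lib$autofluorescence,
                       each = size * size), dim = c(size, size, B))
  attr(af_cube, "wavelengths") <- true_lib$wavelengths
  singles <- lapply(colnames(true_lib$endmembers), function(f) {
    spec <- level * true_lib$endmembers[, f] +
      af_level * true_lib$autofluorescence
    cb <- array(rep(spec, each = size * size), dim = c(size, size, B))
    attr(cb, "wavelengths") <- true_lib$wavelengths
    cb
  })
  names(singles) <- colnames(true_lib$endmembers)
  build_library_from_singleplex(singles, af_cube)
}

pipeline_comparisons <- function(z, roi_means, config) {
  rows <- list()
  pairs <- utils::combn(config$groups, 2, simplify = FALSE)
  specs <- list(c("ndufb8", "deficient"), c("mtco1", "deficient"),
                c("tomm20", "high"))
  for (pr in pairs) {
    for (sp in specs) {
      res <- tryCatch(
        compare_proportions(z, sp[1], sp[2], pr[1], pr[2]),
        error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        test = res$test_name, contrast = res$contrast, marker = res$marker,
        category = res$category, p_a = res$p_a, p_b = res$p_b,
        delta_pp = res$delta_pp, stat = res$chi2_stat, df = res$df,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  for (m in c("ndufb8", "mtco1", "tomm20")) {
    vals <- split(roi_means[[paste0("mean_z_", m)]], roi_means$group)
    res <- tryCatch(kruskal_wallis(vals), error = function(e) NULL)
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      test = res$test_name, contrast = "roi means across groups",
      marker = m, category = "mean_z", p_a = NA_real_, p_b = NA_real_,
      delta_pp = NA_real_, stat = res$chi2_stat, df = res$df,
      p_value = res$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
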