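# Cell segmentation on unmixed component images, tissue classification and
# per-cell quantification.

#' Segmentation parameters
#'
#' @param dapi_sigma Gaussian smoothing SD (px) applied to the DAPI plane
#'   before thresholding.
#' @param dapi_threshold foreground threshold on the smoothed DAPI plane;
#'   `NULL` chooses it automatically (Otsu).
#' @param min_nucleus_area nuclei smaller than this (px) are discarded.
#' @param cyto_radius cytoplasmic expansion distance (px) around each
#'   nucleus; expansion stops at neighbouring cells.
#' @param ck_support_threshold if not `NULL`, cytoplasmic expansion is
#'   restricted to pixels whose cytokeratin component exceeds this value.
#' @param peak_window half-width (px) of the local-maximum window used to
#'   seed the watershed that splits touching nuclei.
#' @return A named list of class `segment_params`.
#' @export
segment_params <- function(dapi_sigma = 1, dapi_threshold = NULL,
                           min_nucleus_area = 4L, cyto_radius = 4L,
                           ck_support_threshold = NULL, peak_window = 2L) {
  p <- list(dapi_sigma = dapi_sigma, dapi_threshold = dapi_threshold,
            min_nucleus_area = as.integer(min_nucleus_area),
            cyto_radius = as.integer(cyto_radius),
            ck_support_threshold = ck_support_threshold,
            peak_window = as.integer(peak_window))
  class(p) <- "segment_params"
  p
}

#' Segment cells from DAPI nuclei with cytoplasmic expansion
#'
#' Nuclei are detected on the DAPI component plane by Gaussian smoothing,
#' (Otsu or supplied) thresholding and a distance-transform watershed that
#' splits touching nuclei. Each nucleus is then grown outward by
#' `cyto_radius` pixels — bounded by neighbouring cells and, optionally, by
#' the cytokeratin-positive support — to form the cytoplasmic footprint.
#' Every emitted label therefore contains at least one nucleus pixel.
#'
#' @param components a `component_images` object (needs a `"DAPI"` plane;
#'   `"Opal690"` is used as the cytokeratin plane when a support threshold
#'   is set).
#' @param params a [segment_params()].
#' @return H x W integer label mask (0 = background, labels contiguous from
#'   1). A blank DAPI plane yields an all-zero mask with a warning.
#' @export
segment_cells <- function(components, params = segment_params()) {
  dapi <- components$planes[["DAPI"]]
  if (is.null(dapi)) stop("components must contain a DAPI plane")
  if (max(dapi) <= .Machine$double.eps) {
    warning("blank DAPI plane; returning empty mask")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  sm <- blur_gaussian(dapi, params$dapi_sigma)
  thr <- if (is.null(params$dapi_threshold)) otsu_threshold(sm) else
    params$dapi_threshold
  fg <- sm > thr
  if (!any(fg)) {
    warning("no DAPI foreground above threshold; returning empty mask")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  # drop specks before seeding
  cc <- label_components(fg)
  sizes <- tabulate(cc[cc > 0])
  fg[cc > 0 & sizes[pmax(cc, 1L)] < params$min_nucleus_area] <- FALSE
  dt <- distance_transform(fg)
  markers <- find_markers(dt, fg, window = params$peak_window)
  nuclei <- .watershed_cpp(dt, markers, fg)
  # cytoplasmic expansion, constrained by neighbours (ties: lowest label)
  allowed <- matrix(TRUE, nrow(dapi), ncol(dapi))
  if (!is.null(params$ck_support_threshold)) {
    ck <- components$planes[["Opal690"]]
    if (is.null(ck)) stop("cytokeratin (Opal690) plane required for ",
                          "ck_support_threshold")
    allowed <- ck > params$ck_support_threshold
  }
  lab <- .propagate_labels_cpp(nuclei, allowed, params$cyto_radius)
  relabel_sequential(lab)
}

relabel_sequential <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (length(u) == 0) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

#' Classify cells as epithelial or stromal from cytokeratin intensity
#'
#' A cell is epithelial iff its mean cytokeratin component intensity is
#' strictly greater than the threshold. With `threshold = NULL` the
#' threshold is chosen by a bimodal (Otsu) split of the per-cell means; if
#' the split does not separate the classes by at least `min_separation`
#' fold the distribution is considered unimodal and an explicit threshold
#' is required.
#'
#' @param components a `component_images` (the `"Opal690"` plane is the
#'   cytokeratin channel).
#' @param mask integer label mask.
#' @param threshold explicit cytokeratin threshold, or `NULL` for
#'   automatic.
#' @param min_separation minimum fold-change between class means for the
#'   automatic split to be accepted.
#' @return Data frame with `label`, `mean_ck`, `tissue_class`
#'   (`"epithelial"` / `"stromal"`) and the threshold used (attribute
#'   `"threshold"`).
#' @export
classify_tissue <- function(components, mask, threshold = NULL,
                            min_separation = 2) {
  ck <- components$planes[["Opal690"]]
  if (is.null(ck)) stop("components must contain a cytokeratin (Opal690) plane")
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0)
    return(structure(data.frame(label = integer(0), mean_ck = numeric(0),
                                tissue_class = character(0)),
                     threshold = threshold))
  mean_ck <- as.numeric(tapply(ck[mask > 0], mask[mask > 0], mean))
  if (is.null(threshold)) {
    # intensities are log-normal; split on the log scale
    eps <- max(mean_ck) * 1e-6 + .Machine$double.xmin
    t_auto <- 10^otsu_threshold(log10(mean_ck + eps))
    lo <- mean_ck[mean_ck <= t_auto]
    hi <- mean_ck[mean_ck > t_auto]
    if (length(lo) == 0 || length(hi) == 0 ||
        mean(hi) < min_separation * max(mean(lo), .Machine$double.eps))
      stop("cytokeratin per-cell means look unimodal; ",
           "supply `threshold` explicitly")
    threshold <- t_auto
  }
  structure(data.frame(label = labs, mean_ck = mean_ck,
                       tissue_class = ifelse(mean_ck > threshold,
                                             "epithelial", "stromal"),
                       stringsAsFactors = FALSE),
            threshold = threshold)
}

#' Quantify per-cell mean component intensities
#'
#' Emits one record per mask label: the mean of each marker component plane
#' over the cell footprint (the per-cell "OD" values), area in pixels,
#' centroid (pixel-centred, origin at the top-left pixel, x rightward, y
#' downward) and an `edge` flag for cells touching the image border.
#'
#' @param components a `component_images`; the autofluorescence plane is
#'   never quantified.
#' @param mask integer label mask of the same shape.
#' @param annotations named list (or one-row data frame) with `patient_id`,
#'   `group`, `roi_id` and `region` for this ROI; missing fields are filled
#'   with `"n/a"` and a warning.
#' @param tissue data frame from [classify_tissue()], joined by label
#'   (optional).
#' @return A cell-table data frame (columns `patient_id`, `group`,
#'   `roi_id`, `region`, `cell_id`, `area_px`, `od_ndufb8`, `od_mtco1`,
#'   `od_tomm20`, `od_ck`, `od_dapi`, `tissue_class`, `cx`, `cy`, `label`,
#'   `edge`).
#' @export
quantify_cells <- function(components, mask, annotations = list(),
                           tissue = NULL) {
  p1 <- components$planes[[1]]
  if (!all(dim(mask) == dim(p1)))
    stop("mask and component planes must share one shape")
  ann <- as.list(annotations)
  absent <- character(0)
  for (f in c("patient_id", "group", "roi_id", "region")) {
    if (is.null(ann[[f]]) || is.na(ann[[f]])) {
      if (f != "region") absent <- c(absent, f)
      ann[[f]] <- "n/a"
    }
  }
  if (length(absent) > 0)
    warning("annotation fields missing, using 'n/a': ",
            paste(absent, collapse = ", "))
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0)
    return(data.frame())
  idx <- which(mask > 0)
  l <- mask[idx]
  fl <- factor(l, levels = labs)
  plane_mean <- function(name) {
    pl <- components$planes[[name]]
    if (is.null(pl)) return(rep(NA_real_, length(labs)))
    as.numeric(tapply(pl[idx], fl, mean))
  }
  rows <- ((idx - 1L) %% nrow(mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(mask)) + 1L
  cx <- as.numeric(tapply(cols - 1L, fl, mean))
  cy <- as.numeric(tapply(rows - 1L, fl, mean))
  edge <- as.logical(tapply(rows == 1L | rows == nrow(mask) |
                              cols == 1L | cols == ncol(mask), fl, any))
  out <- data.frame(
    patient_id = ann$patient_id, group = ann$group, roi_id = ann$roi_id,
    region = ann$region,
    cell_id = sprintf("%s_c%03d", ann$roi_id, labs),
    area_px = as.integer(tabulate(fl)),
    od_ndufb8 = plane_mean(marker_fluorophores[["od_ndufb8"]]),
    od_mtco1 = plane_mean(marker_fluorophores[["od_mtco1"]]),
    od_tomm20 = plane_mean(marker_fluorophores[["od_tomm20"]]),
    od_ck = plane_mean(marker_fluorophores[["od_ck"]]),
    od_dapi = plane_mean(marker_fluorophores[["od_dapi"]]),
    tissue_class = NA_character_,
    cx = cx, cy = cy, label = labs, edge = edge,
    stringsAsFactors = FALSE)
  if (!is.null(tissue)) {
    m <- match(out$label, tissue$label)
    out$tissue_class <- tissue$tissue_class[m]
  }
  out
}
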