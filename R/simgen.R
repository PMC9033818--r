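# Synthetic cohort generator: the generative inverse of the Z-score fitting
# procedure, with known per-cell ground truth.

# number of pixels in a digital disk of radius r (pixel centres)
disk_area_px <- function(r) {
  d <- seq(-r, r)
  sum(outer(d^2, d^2, "+") <= r^2)
}

# relative (dy, dx) offsets of a digital disk
disk_offsets <- function(r) {
  d <- seq(-r, r)
  g <- expand.grid(dy = d, dx = d)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

# grid positions with jitter for n cells inside an H x W frame
place_cells <- function(n, image) {
  margin <- image$cytoplasm_radius + 2L
  s <- image$cell_spacing
  xs <- seq(margin + 1L, image$width - margin, by = s)
  ys <- seq(margin + 1L, image$height - margin, by = s)
  if (length(xs) * length(ys) < n)
    stop(sprintf("cannot place %d cells in a %dx%d image at spacing %d",
                 n, image$height, image$width, s))
  g <- expand.grid(cx = xs, cy = ys)[seq_len(n), , drop = FALSE]
  j <- image$jitter
  if (j > 0) {
    g$cx <- g$cx + sample.int(2L * j + 1L, n, replace = TRUE) - j - 1L
    g$cy <- g$cy + sample.int(2L * j + 1L, n, replace = TRUE) - j - 1L
  }
  g
}

# Assign `count` cells of one phenotype to spatially contiguous clones.
# `candidates`: indices of assignable cells; cx/cy their centroids.
assign_clones <- function(count, candidates, cx, cy, mean_size) {
  chosen <- integer(0)
  free <- candidates
  while (count > 0 && length(free) > 0) {
    size <- min(count, length(free),
                1L + stats::rpois(1, max(mean_size - 1, 0)))
    seed_i <- free[sample.int(length(free), 1L)]
    d <- (cx[free] - cx[seed_i])^2 + (cy[free] - cy[seed_i])^2
    take <- free[order(d, free)][seq_len(size)]
    chosen <- c(chosen, take)
    free <- setdiff(free, take)
    count <- count - size
  }
  chosen
}

#' Simulate a synthetic cell population with known ground truth
#'
#' Draws per-cell marker abundances from the control model declared in the
#' configuration: log10-TOMM20 is Gaussian `N(mu_T, sd_T)`; log10-NDUFB8 and
#' log10-MTCO1 are linear in log10-TOMM20 with Gaussian residuals. Planted
#' phenotypes perturb this model: `ndufb8_deficient` / `mtco1_deficient`
#' shift the relevant residual down by `deficiency_shift` residual SDs
#' (placed in contiguous spatial clones within an ROI) and `high_tomm20`
#' shifts log10-TOMM20 up by `high_tomm20_shift * sd_T`. Stromal cells get
#' near-zero cytokeratin and never carry a planted phenotype.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_population` with elements
#'   \describe{
#'     \item{cells}{data frame, one row per cell: `patient_id`, `group`,
#'       `roi_id`, `region`, `cell_id`, `area_px`, `od_ndufb8`, `od_mtco1`,
#'       `od_tomm20`, `od_ck`, `od_dapi`, plus ground-truth columns
#'       `tissue_class`, `phenotype`, centroid `cx`/`cy` and the within-ROI
#'       mask `label`.}
#'     \item{config}{the configuration used.}
#'   }
#'   Identical configurations (including seed) give identical output.
#' @export
simulate_cell_population <- function(config) {
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  area <- disk_area_px(config$image$cytoplasm_radius)
  rows <- list()
  pat_counter <- 0L
  for (g in config$groups) {
    for (p in seq_len(config$n_patients_per_group)) {
      pat_counter <- pat_counter + 1L
      patient_id <- sprintf("P%02d", pat_counter)
      for (r in seq_len(config$rois_per_patient)) {
        roi_id <- sprintf("%s_R%02d", patient_id, r)
        region <- if (g == "tumour") {
          if (r %% 2L == 1L) "tumour" else "benign_adjacent"
        } else "n/a"
        frac_key <- if (g == "tumour" && region == "benign_adjacent")
          "benign_adjacent" else g
        rows[[roi_id]] <- simulate_roi(config, g, patient_id, roi_id,
                                       region, frac_key, area)
      }
    }
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  cells$cell_id <- sprintf("%s_c%03d", cells$roi_id, cells$label)
  out <- list(cells = cells, config = config)
  class(out) <- "sim_population"
  out
}

simulate_roi <- function(config, group, patient_id, roi_id, region,
                         frac_key, area) {
  n <- config$cells_per_roi
  pos <- place_cells(n, config$image)
  stromal <- runif(n) < config$stromal_fraction
  phenotype <- rep("normal", n)

  f <- config$deficiency_fractions[[frac_key]]
  epi <- which(!stromal)
  if (length(epi) > 0) {
    counts <- drop(stats::rmultinom(1, length(epi),
                                    c(f[["ndufb8"]], f[["mtco1"]],
                                      f[["high_tomm20"]],
                                      1 - sum(f))))
    free <- epi
    for (k in seq_along(c("ndufb8_deficient", "mtco1_deficient"))) {
      ph <- c("ndufb8_deficient", "mtco1_deficient")[k]
      idx <- assign_clones(counts[k], free, pos$cx, pos$cy,
                           config$clonal_cluster_size)
      phenotype[idx] <- ph
      free <- setdiff(free, idx)
    }
    # high-TOMM20 cells are not described as clonal; assign at random
    if (counts[3] > 0 && length(free) > 0) {
      idx <- free[sample.int(length(free), min(counts[3], length(free)))]
      phenotype[idx] <- "high_tomm20"
    }
  }

  log_T <- rnorm(n, config$mu_T, config$sd_T) +
    ifelse(phenotype == "high_tomm20",
           config$high_tomm20_shift * config$sd_T, 0)
  eps_N <- if (config$resid_sd_N > 0) rnorm(n, 0, config$resid_sd_N) else
    numeric(n)
  eps_M <- if (config$resid_sd_M > 0) rnorm(n, 0, config$resid_sd_M) else
    numeric(n)
  eps_N <- eps_N - ifelse(phenotype == "ndufb8_deficient",
                          config$deficiency_shift * config$resid_sd_N, 0)
  eps_M <- eps_M - ifelse(phenotype == "mtco1_deficient",
                          config$deficiency_shift * config$resid_sd_M, 0)
  log_N <- config$intercept_N + config$slope_N * log_T + eps_N
  log_M <- config$intercept_M + config$slope_M * log_T + eps_M
  od_ck <- 10^ifelse(stromal,
                     rnorm(n, config$ck_log_mean_stromal,
                           config$ck_log_sd_stromal),
                     rnorm(n, config$ck_log_mean_epithelial,
                           config$ck_log_sd_epithelial))
  od_dapi <- 10^rnorm(n, config$dapi_log_mean, config$dapi_log_sd)

  data.frame(patient_id = patient_id, group = group, roi_id = roi_id,
             region = region, cell_id = NA_character_,
             label = seq_len(n), area_px = area,
             od_ndufb8 = 10^log_N, od_mtco1 = 10^log_M,
             od_tomm20 = 10^log_T, od_ck = od_ck, od_dapi = od_dapi,
             tissue_class = ifelse(stromal, "stromal", "epithelial"),
             phenotype = phenotype,
             cx = pos$cx, cy = pos$cy,
             stringsAsFactors = FALSE)
}

# deterministic per-ROI RNG stream: polynomial string hash folded into the
# configured seed, kept within the 32-bit seed range
roi_render_seed <- function(seed, roi_tag) {
  h <- 0
  for (ch in utf8ToInt(roi_tag)) h <- (h * 31 + ch) %% 1048573
  as.integer((abs(seed) * 1048573 + h) %% .Machine$integer.max)
}

# marker -> fluorophore channel assignment used by the renderer
marker_fluorophores <- c(od_dapi = "DAPI", od_ndufb8 = "Opal520",
                         od_mtco1 = "Opal570", od_tomm20 = "Opal620",
                         od_ck = "Opal690")

#' Render one ROI as a multispectral cube with paired label mask
#'
#' Each cell is stamped as a circular cytoplasmic footprint carrying its
#' NDUFB8, MTCO1, TOMM20 and cytokeratin abundances uniformly, plus a
#' nuclear DAPI disk whose amplitude is scaled so the footprint-mean DAPI
#' equals the cell's `od_dapi`. The noiseless pixel spectrum is the linear
#' mixture `sum_f abundance_f * endmember_f + af_level * autofluorescence`;
#' optional Poisson shot noise and Gaussian read noise are then applied.
#' Overlapping footprints resolve deterministically to the lowest label and
#' raise a warning.
#'
#' @param cells per-ROI rows of [simulate_cell_population()] output
#'   (columns `label`, `cx`, `cy` and the five `od_*` columns).
#' @param library a `spectral_library` whose fluorophores cover the
#'   renderer's channel assignment (DAPI, Opal520/570/620/690).
#' @param config a [sim_config()]; `config$image` controls geometry,
#'   autofluorescence level and the noise model.
#' @return A list of class `tissue_cube`: `cube` (H x W x B array, bands in
#'   `wavelengths` order), `mask` (H x W integer matrix, 0 = background,
#'   cell labels as in `cells$label`), `wavelengths`.
#' @export
render_tissue_cube <- function(cells, library, config) {
  validate_spectral_library(library)
  # noise is reproducible: seeded from the config seed and the ROI id
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  roi_tag <- if ("roi_id" %in% names(cells) && nrow(cells) > 0)
    cells$roi_id[1] else ""
  set.seed(roi_render_seed(config$seed, roi_tag))
  img <- config$image
  need <- unname(marker_fluorophores)
  if (!all(need %in% colnames(library$endmembers)))
    stop("library must contain fluorophores: ", paste(need, collapse = ", "))
  H <- img$height; W <- img$width
  if (any(cells$cx < 1 + img$cytoplasm_radius) ||
      any(cells$cx > W - img$cytoplasm_radius) ||
      any(cells$cy < 1 + img$cytoplasm_radius) ||
      any(cells$cy > H - img$cytoplasm_radius))
    stop("cell positions do not fit in the image")

  fl_names <- colnames(library$endmembers)
  planes <- lapply(fl_names, function(f) matrix(0, H, W))
  names(planes) <- fl_names
  mask <- matrix(0L, H, W)

  cyto <- disk_offsets(img$cytoplasm_radius)
  nuc <- disk_offsets(img$nucleus_radius)
  dapi_scale <- nrow(cyto) / nrow(nuc)
  overlap <- 0L

  ord <- order(cells$label)
  for (i in ord) {
    ci <- cells[i, ]
    fy <- ci$cy + cyto$dy; fx <- ci$cx + cyto$dx
    idx <- cbind(fy, fx)
    taken <- mask[idx] != 0L
    overlap <- overlap + sum(taken)
    mask[idx[!taken, , drop = FALSE]] <- ci$label
    for (m in c("od_ndufb8", "od_mtco1", "od_tomm20", "od_ck")) {
      f <- marker_fluorophores[[m]]
      planes[[f]][idx] <- planes[[f]][idx] + ci[[m]]
    }
    nidx <- cbind(ci$cy + nuc$dy, ci$cx + nuc$dx)
    planes[["DAPI"]][nidx] <- planes[["DAPI"]][nidx] + ci$od_dapi * dapi_scale
  }
  if (overlap > 0)
    warning(sprintf("%d overlapping footprint pixels; lowest label kept",
                    overlap))

  B <- length(library$wavelengths)
  A <- cbind(do.call(cbind, lapply(planes, as.vector)),
             rep(img$af_level, H * W))
  S <- cbind(library$endmembers, library$autofluorescence)
  cube <- array(A %*% t(S), dim = c(H, W, B))

  if (img$noise_model != "none") {
    cube <- array(rpois(length(cube), img$gain * cube) / img$gain,
                  dim = dim(cube))
    if (img$noise_model == "poisson_gaussian" && img$read_sd > 0)
      cube <- pmax(cube + array(rnorm(length(cube), 0, img$read_sd),
                                dim = dim(cube)), 0)
  }
  out <- list(cube = cube, mask = mask, wavelengths = library$wavelengths)
  class(out) <- "tissue_cube"
  out
}

#' Write / read a cell table as CSV
#' @param cells a cell table data frame.
#' @param path file path.
#' @return `read_cell_table` returns a data frame; `write_cell_table`
#'   returns `path` invisibly.
#' @export
write_cell_table <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
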