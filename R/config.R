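#' Imaging geometry and acquisition settings for the synthetic renderer
#'
#' Geometry is in pixels of a 20x field. Cells are stamped as a nuclear disk
#' (DAPI) inside a circular cytoplasmic footprint carrying the mitochondrial
#' and cytokeratin signal. The noise model is the standard fluorescence
#' camera model: Poisson shot noise on expected photon counts (intensity
#' times `gain`) plus additive Gaussian read noise.
#'
#' @param height,width image size in pixels.
#' @param nucleus_radius,cytoplasm_radius disk radii in pixels; the
#'   cytoplasmic footprint must contain the nucleus.
#' @param cell_spacing centre-to-centre grid spacing used to place cells.
#' @param jitter maximum uniform perturbation (px) applied to grid positions.
#' @param af_level uniform autofluorescence abundance added to every pixel.
#' @param noise_model one of `"none"`, `"poisson"`, `"poisson_gaussian"`.
#' @param gain photons per intensity unit for the shot-noise model.
#' @param read_sd standard deviation of the Gaussian read noise
#'   (intensity units).
#' @return A named list of class `image_config`.
#' @export
image_config <- function(height = 288L, width = 288L,
                         nucleus_radius = 3L, cytoplasm_radius = 6L,
                         cell_spacing = 16L, jitter = 1L,
                         af_level = 0.2,
                         noise_model = c("poisson_gaussian", "poisson", "none"),
                         gain = 100, read_sd = 0.01) {
  noise_model <- match.arg(noise_model)
  cfg <- list(height = as.integer(height), width = as.integer(width),
              nucleus_radius = as.integer(nucleus_radius),
              cytoplasm_radius = as.integer(cytoplasm_radius),
              cell_spacing = as.integer(cell_spacing),
              jitter = as.integer(jitter),
              af_level = af_level, noise_model = noise_model,
              gain = gain, read_sd = read_sd)
  if (cfg$height < 16 || cfg$width < 16)
    stop("image must be at least 16x16 pixels")
  if (cfg$nucleus_radius < 1 || cfg$cytoplasm_radius <= cfg$nucleus_radius)
    stop("cytoplasm_radius must exceed nucleus_radius >= 1")
  if (cfg$af_level < 0 || cfg$gain <= 0 || cfg$read_sd < 0)
    stop("af_level/read_sd must be >= 0 and gain > 0")
  class(cfg) <- "image_config"
  cfg
}

#' Per-group phenotype fractions used by the simulator
#'
#' Default fractions mirror the cohort-level frequencies reported for benign
#' prostate from young men, age-matched benign prostate, and prostate
#' cancer: NDUFB8-deficient 0.23%/0.61%/15.68%, MTCO1-deficient
#' 0.277%/4.52%/1.38%, high-TOMM20 0.82%/4.26%/11.87%. The extra
#' `benign_adjacent` entry applies to benign-adjacent regions within
#' tumour-group patients (0.059%/0.16%/6.49%).
#'
#' @return Named list; each element is a numeric vector with entries
#'   `ndufb8`, `mtco1`, `high_tomm20` (fractions in `[0, 1]`).
#' @export
default_deficiency_fractions <- function() {
  list(
    young_benign    = c(ndufb8 = 0.0023,  mtco1 = 0.00277, high_tomm20 = 0.0082),
    aged_benign     = c(ndufb8 = 0.0061,  mtco1 = 0.0452,  high_tomm20 = 0.0426),
    tumour          = c(ndufb8 = 0.1568,  mtco1 = 0.0138,  high_tomm20 = 0.1187),
    benign_adjacent = c(ndufb8 = 0.00059, mtco1 = 0.0016,  high_tomm20 = 0.0649)
  )
}

#' Simulation configuration
#'
#' The generative model is the exact inverse of the fitting procedure used
#' downstream: in control cells log10-TOMM20 is Gaussian and log10-NDUFB8 /
#' log10-MTCO1 are linear in log10-TOMM20 with Gaussian residuals. Deficient
#' phenotypes shift the relevant marker's residual down by
#' `deficiency_shift` residual SDs; high-TOMM20 cells shift log10-TOMM20 up
#' by `high_tomm20_shift` times `sd_T`. Deficient cells are planted in
#' spatially contiguous clones within each region of interest (ROI).
#'
#' @param seed integer RNG seed; identical configurations produce identical
#'   populations, cubes and masks.
#' @param groups patient group labels; `"young_benign"` is the control
#'   cohort, `"tumour"` patients carry tumour and benign-adjacent ROIs.
#' @param n_patients_per_group,rois_per_patient,cells_per_roi cohort sizes.
#' @param mu_T,sd_T mean and SD of control log10-TOMM20.
#' @param slope_N,intercept_N,resid_sd_N control regression of log10-NDUFB8
#'   on log10-TOMM20 (residual SD may be 0 for noiseless oracles).
#' @param slope_M,intercept_M,resid_sd_M same for log10-MTCO1.
#' @param deficiency_fractions see [default_deficiency_fractions()];
#'   per group the three fractions must sum to at most 1.
#' @param deficiency_shift downward residual shift, in residual-SD units.
#' @param high_tomm20_shift upward shift of log10-TOMM20 in `sd_T` units.
#' @param clonal_cluster_size mean number of cells per deficient clone.
#' @param stromal_fraction fraction of simulated cells that are stromal
#'   (near-zero cytokeratin, excluded from phenotype planting).
#' @param ck_log_mean_epithelial,ck_log_sd_epithelial,ck_log_mean_stromal,ck_log_sd_stromal
#'   log10 cytokeratin abundance model for the two tissue classes.
#' @param dapi_log_mean,dapi_log_sd log10 DAPI abundance model.
#' @param image an [image_config()].
#' @return A list of class `sim_config`.
#' @seealso [simulate_cell_population()], [render_tissue_cube()]
#' @export
sim_config <- function(seed = 1L,
                       groups = c("young_benign", "aged_benign", "tumour"),
                       n_patients_per_group = 2L,
                       rois_per_patient = 4L,
                       cells_per_roi = 200L,
                       mu_T = 2.0, sd_T = 0.2,
                       slope_N = 0.9, intercept_N = 0.5, resid_sd_N = 0.05,
                       slope_M = 0.95, intercept_M = 0.3, resid_sd_M = 0.06,
                       deficiency_fractions = default_deficiency_fractions(),
                       deficiency_shift = 5,
                       high_tomm20_shift = 3,
                       clonal_cluster_size = 10,
                       stromal_fraction = 0.25,
                       ck_log_mean_epithelial = 1.0, ck_log_sd_epithelial = 0.1,
                       ck_log_mean_stromal = -1.0, ck_log_sd_stromal = 0.2,
                       dapi_log_mean = 0.8, dapi_log_sd = 0.1,
                       image = image_config()) {
  cfg <- list(seed = as.integer(seed), groups = as.character(groups),
              n_patients_per_group = as.integer(n_patients_per_group),
              rois_per_patient = as.integer(rois_per_patient),
              cells_per_roi = as.integer(cells_per_roi),
              mu_T = mu_T, sd_T = sd_T,
              slope_N = slope_N, intercept_N = intercept_N,
              resid_sd_N = resid_sd_N,
              slope_M = slope_M, intercept_M = intercept_M,
              resid_sd_M = resid_sd_M,
              deficiency_fractions = deficiency_fractions,
              deficiency_shift = deficiency_shift,
              high_tomm20_shift = high_tomm20_shift,
              clonal_cluster_size = clonal_cluster_size,
              stromal_fraction = stromal_fraction,
              ck_log_mean_epithelial = ck_log_mean_epithelial,
              ck_log_sd_epithelial = ck_log_sd_epithelial,
              ck_log_mean_stromal = ck_log_mean_stromal,
              ck_log_sd_stromal = ck_log_sd_stromal,
              dapi_log_mean = dapi_log_mean, dapi_log_sd = dapi_log_sd,
              image = if (inherits(image, "image_config")) image
                      else do.call(image_config, image))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$groups) >= 1, !anyDuplicated(cfg$groups),
            cfg$n_patients_per_group >= 1, cfg$rois_per_patient >= 1,
            cfg$cells_per_roi >= 1)
  if (cfg$sd_T <= 0) stop("sd_T must be > 0")
  if (cfg$resid_sd_N < 0 || cfg$resid_sd_M < 0)
    stop("residual SDs must be >= 0")
  if (cfg$stromal_fraction < 0 || cfg$stromal_fraction >= 1)
    stop("stromal_fraction must be in [0, 1)")
  if (cfg$clonal_cluster_size < 1) stop("clonal_cluster_size must be >= 1")
  needed <- unique(c(cfg$groups,
                     if ("tumour" %in% cfg$groups) "benign_adjacent"))
  for (g in needed) {
    f <- cfg$deficiency_fractions[[g]]
    if (is.null(f))
      stop("deficiency_fractions missing entry for '", g, "'")
    if (!all(c("ndufb8", "mtco1", "high_tomm20") %in% names(f)))
      stop("deficiency_fractions[['", g,
           "']] needs ndufb8, mtco1 and high_tomm20")
    if (any(f < 0) || any(f > 1))
      stop("phenotype fractions must lie in [0, 1]")
    if (sum(f) > 1)
      stop("phenotype fractions for '", g, "' sum to more than 1")
  }
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path file path.
#' @param cfg a [sim_config()].
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$deficiency_fractions))
    raw$deficiency_fractions <- lapply(raw$deficiency_fractions, unlist)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- unclass(cfg)
  out$image <- unclass(out$image)
  out$deficiency_fractions <- lapply(out$deficiency_fractions, as.list)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  n_cells <- length(x$groups) * x$n_patients_per_group *
    x$rois_per_patient * x$cells_per_roi
  cat("Simulation configuration\n")
  cat(sprintf("  groups: %s\n", paste(x$groups, collapse = ", ")))
  cat(sprintf("  %d patients/group x %d ROIs x %d cells (total %d cells)\n",
              x$n_patients_per_group, x$rois_per_patient, x$cells_per_roi,
              n_cells))
  cat(sprintf("  control model: log10 T ~ N(%.3g, %.3g); N: %.3g + %.3g T (sd %.3g); M: %.3g + %.3g T (sd %.3g)\n",
              x$mu_T, x$sd_T, x$intercept_N, x$slope_N, x$resid_sd_N,
              x$intercept_M, x$slope_M, x$resid_sd_M))
  cat(sprintf("  image: %dx%d px, noise '%s'\n", x$image$height,
              x$image$width, x$image$noise_model))
  invisible(x)
}
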