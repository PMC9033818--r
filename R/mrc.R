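# Control-cohort model fitting, per-cell Z-scores and abundance
# classification: the core statistic of the pipeline.

#' Fit the control model on young-benign epithelial cells
#'
#' Log10-transforms the per-cell marker intensities and fits, by ordinary
#' least squares, log10-NDUFB8 and log10-MTCO1 (dependent) against
#' log10-TOMM20 (independent) on control cells, together with the mean and
#' SD of control log10-TOMM20. Residual SDs use the n-2 denominator of the
#' fitted regressions. Cells with any nonpositive marker intensity cannot
#' be log-transformed and are excluded (their count is recorded).
#'
#' @param cells a cell table. If it carries `group` / `tissue_class`
#'   columns, rows are first filtered to `control_group` and (when present)
#'   to epithelial cells; otherwise all rows are treated as controls.
#' @param min_n minimum number of usable control cells.
#' @param control_group label of the control cohort.
#' @return An object of class `control_model`: `mu_T`, `sd_T`,
#'   `intercept_N`, `slope_N`, `resid_sd_N`, `intercept_M`, `slope_M`,
#'   `resid_sd_M`, `n_control`, `n_excluded`, plus the OLS standard errors
#'   (`se_slope_N`, `se_intercept_N`, `se_slope_M`, `se_intercept_M`).
#' @export
fit_control_model <- function(cells, min_n = 100L,
                              control_group = "young_benign") {
  ctrl <- cells
  if ("group" %in% names(ctrl) && any(ctrl$group == control_group))
    ctrl <- ctrl[ctrl$group == control_group, , drop = FALSE]
  if ("tissue_class" %in% names(ctrl) &&
      any(ctrl$tissue_class == "epithelial", na.rm = TRUE))
    ctrl <- ctrl[!is.na(ctrl$tissue_class) &
                   ctrl$tissue_class == "epithelial", , drop = FALSE]
  ok <- ctrl$od_ndufb8 > 0 & ctrl$od_mtco1 > 0 & ctrl$od_tomm20 > 0
  n_excluded <- sum(!ok)
  ctrl <- ctrl[ok, , drop = FALSE]
  n <- nrow(ctrl)
  if (n < min_n)
    stop(sprintf("insufficient control cells: %d usable, need >= %d",
                 n, min_n))
  lT <- log10(ctrl$od_tomm20)
  lN <- log10(ctrl$od_ndufb8)
  lM <- log10(ctrl$od_mtco1)
  fit_one <- function(y) {
    fit <- lm(y ~ lT)
    s <- suppressWarnings(summary(fit))  # perfect fits warn; caught below
    sigma <- s$sigma                       # sqrt(RSS / (n - 2))
    if (!is.finite(sigma) || sigma < 1e-12)
      stop("degenerate control model: residual SD is (near) zero")
    list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
         resid_sd = sigma,
         se_intercept = s$coefficients[1, 2],
         se_slope = s$coefficients[2, 2])
  }
  fN <- fit_one(lN)
  fM <- fit_one(lM)
  model <- list(mu_T = mean(lT), sd_T = sd(lT),
                intercept_N = fN$intercept, slope_N = fN$slope,
                resid_sd_N = fN$resid_sd,
                intercept_M = fM$intercept, slope_M = fM$slope,
                resid_sd_M = fM$resid_sd,
                se_intercept_N = fN$se_intercept, se_slope_N = fN$se_slope,
                se_intercept_M = fM$se_intercept, se_slope_M = fM$se_slope,
                n_control = n, n_excluded = n_excluded)
  if (model$sd_T < 1e-12)
    stop("degenerate control model: log10-TOMM20 SD is (near) zero")
  class(model) <- "control_model"
  model
}

#' @export
print.control_model <- function(x, ...) {
  cat("Control model (", x$n_control, " cells)\n", sep = "")
  cat(sprintf("  log10 TOMM20: mean %.4f, SD %.4f\n", x$mu_T, x$sd_T))
  cat(sprintf("  log10 NDUFB8 = %.4f + %.4f x log10 TOMM20  (resid SD %.4f)\n",
              x$intercept_N, x$slope_N, x$resid_sd_N))
  cat(sprintf("  log10 MTCO1  = %.4f + %.4f x log10 TOMM20  (resid SD %.4f)\n",
              x$intercept_M, x$slope_M, x$resid_sd_M))
  invisible(x)
}

#' Read / write a control model as YAML
#' @param model a `control_model`.
#' @param path file path.
#' @return `read_control_model` returns a `control_model`;
#'   `write_control_model` returns `path` invisibly.
#' @export
write_control_model <- function(model, path) {
  stopifnot(inherits(model, "control_model"))
  yaml::write_yaml(unclass(model), path, precision = 15)
  invisible(path)
}

#' @rdname write_control_model
#' @export
read_control_model <- function(path) {
  model <- yaml::read_yaml(path)
  class(model) <- "control_model"
  model
}

#' Compute per-cell Z-scores against a control model
#'
#' `z_tomm20 = (log10 OD_T - mu_T) / sd_T`; `z_ndufb8` and `z_mtco1` are
#' the deviations of log10-NDUFB8 / log10-MTCO1 from their regression
#' expectations given the cell's log10-TOMM20, in residual-SD units.
#'
#' @param cells a cell table.
#' @param model a `control_model`.
#' @param exclusion_policy how to treat cells with a nonpositive marker
#'   intensity: `"drop"` removes them (count in attribute `"n_excluded"`),
#'   `"floor"` replaces nonpositive values by `floor_value` first.
#' @param floor_value positive floor used by the `"floor"` policy.
#' @return The input rows (minus exclusions) with `z_ndufb8`, `z_mtco1`
#'   and `z_tomm20` columns appended; attribute `"n_excluded"` carries the
#'   number of dropped cells.
#' @export
compute_zscores <- function(cells, model,
                            exclusion_policy = c("drop", "floor"),
                            floor_value = 1e-6) {
  exclusion_policy <- match.arg(exclusion_policy)
  stopifnot(inherits(model, "control_model"))
  od <- cells[, c("od_ndufb8", "od_mtco1", "od_tomm20")]
  n_excluded <- 0L
  if (exclusion_policy == "drop") {
    ok <- od$od_ndufb8 > 0 & od$od_mtco1 > 0 & od$od_tomm20 > 0
    n_excluded <- sum(!ok)
    cells <- cells[ok, , drop = FALSE]
  } else {
    stopifnot(floor_value > 0)
    for (cn in c("od_ndufb8", "od_mtco1", "od_tomm20"))
      cells[[cn]] <- pmax(cells[[cn]], floor_value)
  }
  lT <- log10(cells$od_tomm20)
  cells$z_ndufb8 <- (log10(cells$od_ndufb8) -
                       (model$intercept_N + model$slope_N * lT)) /
    model$resid_sd_N
  cells$z_mtco1 <- (log10(cells$od_mtco1) -
                      (model$intercept_M + model$slope_M * lT)) /
    model$resid_sd_M
  cells$z_tomm20 <- (lT - model$mu_T) / model$sd_T
  attr(cells, "n_excluded") <- n_excluded
  cells
}

#' Category thresholds for Z-score classification
#'
#' NDUFB8/MTCO1: `very_low` iff z < -6; `low` iff -6 <= z < -3; `normal`
#' iff -3 <= z <= 3; `high` iff z > 3 (the `very_low` and `low` bands
#' overlap as stated verbally; precedence goes to `very_low` so the bands
#' partition the line). TOMM20: `low` iff z < -2; `normal` iff
#' -2 <= z <= 2; `high` iff z > 2. A cell is deficient in a marker iff
#' that marker's z is strictly below -3.
#'
#' @param marker_very_low,marker_low,marker_high NDUFB8/MTCO1 cut points.
#' @param tomm20_low,tomm20_high TOMM20 cut points.
#' @param deficient deficiency cut point (strict `<`).
#' @return Named list of thresholds.
#' @export
z_thresholds <- function(marker_very_low = -6, marker_low = -3,
                         marker_high = 3, tomm20_low = -2, tomm20_high = 2,
                         deficient = -3) {
  list(marker_very_low = marker_very_low, marker_low = marker_low,
       marker_high = marker_high, tomm20_low = tomm20_low,
       tomm20_high = tomm20_high, deficient = deficient)
}

classify_marker_z <- function(z, th) {
  out <- rep(NA_character_, length(z))
  fin <- is.finite(z)
  out[fin & z < th$marker_very_low] <- "very_low"
  out[fin & z >= th$marker_very_low & z < th$marker_low] <- "low"
  out[fin & z >= th$marker_low & z <= th$marker_high] <- "normal"
  out[fin & z > th$marker_high] <- "high"
  out
}

classify_tomm20_z <- function(z, th) {
  out <- rep(NA_character_, length(z))
  fin <- is.finite(z)
  out[fin & z < th$tomm20_low] <- "low"
  out[fin & z >= th$tomm20_low & z <= th$tomm20_high] <- "normal"
  out[fin & z > th$tomm20_high] <- "high"
  out
}

#' Classify scored cells into abundance categories
#'
#' Appends `cat_ndufb8`, `cat_mtco1` (`very_low`/`low`/`normal`/`high`),
#' `cat_tomm20` (`low`/`normal`/`high`), boolean `deficient_ndufb8` /
#' `deficient_mtco1` (z strictly below -3) and an `invalid` flag for cells
#' with any non-finite z (their categories are `NA` and they are excluded
#' from downstream proportions; attribute `"n_invalid"` carries the
#' count).
#'
#' @param z_records output of [compute_zscores()].
#' @param thresholds a [z_thresholds()] list.
#' @return `z_records` with classification columns appended.
#' @export
classify_cells <- function(z_records, thresholds = z_thresholds()) {
  th <- thresholds
  z_records$cat_ndufb8 <- classify_marker_z(z_records$z_ndufb8, th)
  z_records$cat_mtco1 <- classify_marker_z(z_records$z_mtco1, th)
  z_records$cat_tomm20 <- classify_tomm20_z(z_records$z_tomm20, th)
  z_records$deficient_ndufb8 <- is.finite(z_records$z_ndufb8) &
    z_records$z_ndufb8 < th$deficient
  z_records$deficient_mtco1 <- is.finite(z_records$z_mtco1) &
    z_records$z_mtco1 < th$deficient
  z_records$invalid <- !is.finite(z_records$z_ndufb8) |
    !is.finite(z_records$z_mtco1) | !is.finite(z_records$z_tomm20)
  attr(z_records, "n_invalid") <- sum(z_records$invalid)
  z_records
}
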