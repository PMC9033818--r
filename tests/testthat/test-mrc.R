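# Control model fitting, Z-scores and abundance classification.

control_table <- function(n, seed = 1L, mu_T = 2, sd_T = 0.2,
                          intercept_N = 0.5, slope_N = 0.9,
                          resid_sd_N = 0.05, intercept_M = 0.3,
                          slope_M = 0.95, resid_sd_M = 0.06) {
  set.seed(seed)
  lT <- rnorm(n, mu_T, sd_T)
  lN <- intercept_N + slope_N * lT + rnorm(n, 0, resid_sd_N)
  lM <- intercept_M + slope_M * lT + rnorm(n, 0, resid_sd_M)
  data.frame(cell_id = sprintf("c%06d", seq_len(n)), area_px = 113L,
             od_ndufb8 = 10^lN, od_mtco1 = 10^lM, od_tomm20 = 10^lT)
}

test_that("OLS fit recovers the generating parameters", {
  cells <- control_table(5000, seed = 3L)
  m <- fit_control_model(cells)
  expect_lt(abs(m$slope_N - 0.9), 3 * m$se_slope_N)
  expect_lt(abs(m$intercept_N - 0.5), 3 * m$se_intercept_N)
  expect_lt(abs(m$slope_M - 0.95), 3 * m$se_slope_M)
  expect_lt(abs(m$resid_sd_N - 0.05) / 0.05, 0.10)
  expect_lt(abs(m$resid_sd_M - 0.06) / 0.06, 0.10)
  expect_lt(abs(m$mu_T - 2), 3 * 0.2 / sqrt(5000))
  expect_equal(m$n_control, 5000L)
})

test_that("degenerate and undersized control sets error", {
  cells <- control_table(200, seed = 4L, resid_sd_N = 0, resid_sd_M = 0)
  expect_error(fit_control_model(cells), "degenerate")
  expect_error(fit_control_model(control_table(99)), "insufficient")
  expect_silent(invisible(fit_control_model(control_table(100),
                                            min_n = 100)))
})

test_that("z-score arithmetic matches its definition", {
  m <- structure(list(mu_T = 2, sd_T = 0.2, intercept_N = 0.5,
                      slope_N = 0.9, resid_sd_N = 0.05, intercept_M = 0.3,
                      slope_M = 0.95, resid_sd_M = 0.06),
                 class = "control_model")
  # cell on both regression lines with log10 OD_T = mu_T
  on_line <- data.frame(cell_id = "a", od_tomm20 = 10^2,
                        od_ndufb8 = 10^(0.5 + 0.9 * 2),
                        od_mtco1 = 10^(0.3 + 0.95 * 2))
  z <- compute_zscores(on_line, m)
  expect_equal(c(z$z_ndufb8, z$z_mtco1, z$z_tomm20), c(0, 0, 0),
               tolerance = 1e-12)
  # mu_T = 2, sd_T = 0.2, log10 OD_T = 2.4 -> z_tomm20 = 2
  shifted <- on_line
  shifted$od_tomm20 <- 10^2.4
  expect_equal(compute_zscores(shifted, m)$z_tomm20, 2, tolerance = 1e-12)
})

test_that("self-scored controls have z mean ~0 and SD ~1", {
  cells <- control_table(10000, seed = 5L)
  m <- fit_control_model(cells)
  z <- compute_zscores(cells, m)
  for (zz in list(z$z_ndufb8, z$z_mtco1, z$z_tomm20)) {
    expect_lt(abs(mean(zz)), 0.02)
    expect_lt(abs(sd(zz) - 1), 0.02)
  }
})

test_that("exclusion policies handle nonpositive intensities", {
  m <- fit_control_model(control_table(500, seed = 6L))
  cells <- control_table(10, seed = 7L)
  cells$od_ndufb8[3] <- 0
  cells$od_tomm20[5] <- -1
  z <- compute_zscores(cells, m, exclusion_policy = "drop")
  expect_equal(nrow(z), 8L)
  expect_equal(attr(z, "n_excluded"), 2L)
  zf <- compute_zscores(cells, m, exclusion_policy = "floor",
                        floor_value = 1e-6)
  expect_equal(nrow(zf), 10L)
  expect_true(all(is.finite(zf$z_ndufb8)))
})

test_that("classification partitions every finite z exactly once", {
  eps <- 1e-9
  zs <- c(outer(c(0, 2, 3, 6), c(-1, 1)), outer(c(0, 2, 3, 6), c(-1, 1)) +
            eps, outer(c(0, 2, 3, 6), c(-1, 1)) - eps)
  rec <- data.frame(cell_id = seq_along(zs), z_ndufb8 = zs, z_mtco1 = zs,
                    z_tomm20 = zs)
  out <- classify_cells(rec)
  # exactly one category per marker per cell
  expect_false(anyNA(out$cat_ndufb8))
  expect_false(anyNA(out$cat_tomm20))
  # category definitions
  expect_identical(out$cat_ndufb8[zs < -6], rep("very_low", sum(zs < -6)))
  expect_identical(out$cat_ndufb8[zs >= -6 & zs < -3],
                   rep("low", sum(zs >= -6 & zs < -3)))
  expect_identical(out$cat_ndufb8[zs >= -3 & zs <= 3],
                   rep("normal", sum(zs >= -3 & zs <= 3)))
  expect_identical(out$cat_ndufb8[zs > 3], rep("high", sum(zs > 3)))
  expect_identical(out$cat_tomm20[zs < -2], rep("low", sum(zs < -2)))
  expect_identical(out$cat_tomm20[zs >= -2 & zs <= 2],
                   rep("normal", sum(zs >= -2 & zs <= 2)))
  expect_identical(out$cat_tomm20[zs > 2], rep("high", sum(zs > 2)))
  # deficiency is strictly z < -3
  expect_identical(out$deficient_ndufb8, zs < -3)
})

test_that("named boundary cases classify as stated", {
  rec <- data.frame(cell_id = 1:4,
                    z_ndufb8 = c(-6.5, -4, 0, 0),
                    z_mtco1 = c(0, 0, -3, 0),
                    z_tomm20 = c(0, 0, 0, 2.5))
  out <- classify_cells(rec)
  expect_identical(out$cat_ndufb8[1], "very_low")
  expect_true(out$deficient_ndufb8[1])
  expect_identical(out$cat_ndufb8[2], "low")
  expect_true(out$deficient_ndufb8[2])
  expect_identical(out$cat_mtco1[3], "normal")   # -3 exactly: not deficient
  expect_false(out$deficient_mtco1[3])
  expect_identical(out$cat_tomm20[4], "high")
})

test_that("non-finite z flags the cell invalid", {
  rec <- data.frame(cell_id = 1:2, z_ndufb8 = c(NaN, 1),
                    z_mtco1 = c(0, 1), z_tomm20 = c(0, 1))
  out <- classify_cells(rec)
  expect_identical(out$invalid, c(TRUE, FALSE))
  expect_identical(attr(out, "n_invalid"), 1L)
  expect_true(is.na(out$cat_ndufb8[1]))
})

test_that("z_ndufb8 is strictly increasing in OD_N, all else fixed", {
  m <- fit_control_model(control_table(500, seed = 8L))
  od <- 10^seq(1.5, 3, length.out = 50)
  cells <- data.frame(cell_id = seq_along(od), od_ndufb8 = od,
                      od_mtco1 = 100, od_tomm20 = 100)
  z <- compute_zscores(cells, m)
  expect_true(all(diff(z$z_ndufb8) > 0))
})

test_that("control model YAML round-trips", {
  m <- fit_control_model(control_table(500, seed = 9L))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_control_model(m, path)
  m2 <- read_control_model(path)
  cells <- control_table(50, seed = 10L)
  expect_equal(compute_zscores(cells, m2)$z_ndufb8,
               compute_zscores(cells, m)$z_ndufb8, tolerance = 1e-9)
})

test_that("simulated cohort filtering picks young-benign epithelial controls", {
  cfg <- noiseless_config(cells_per_roi = 300L, rois_per_patient = 2L,
                          deficiency_fractions = zero_fractions())
  pop <- simulate_cell_population(cfg)
  m <- fit_control_model(pop$cells)
  n_young_epi <- sum(pop$cells$group == "young_benign" &
                       pop$cells$tissue_class == "epithelial")
  expect_equal(m$n_control, n_young_epi)
})
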