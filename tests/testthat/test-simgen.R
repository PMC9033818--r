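# Synthetic-data generator: spectral library, cell population, renderer.

test_that("spectral library has the expected grid and unit-peak spectra", {
  lib <- make_spectral_library(440, 720, 20)
  expect_length(lib$wavelengths, 15L)
  expect_equal(unname(apply(lib$endmembers, 2, max)),
               rep(1, ncol(lib$endmembers)))
  expect_gt(min(lib$endmembers), -1e-300)  # nonnegative
  # pairwise distinct endmembers
  cs <- crossprod(lib$endmembers)
  expect_true(all(abs(cs[upper.tri(cs)] / diag(cs)[1]) < 1))
})

test_that("spectral library rejects bad grids and duplicate names", {
  expect_error(make_spectral_library(440, 720, 23), "divide")
  expect_error(make_spectral_library(
    peak_positions = c(A = 500, A = 550)), "unique")
  expect_error(make_spectral_library(
    peak_positions = c(DAPI = 100)), "within the band range")
})

test_that("endmembers 60 nm apart at width 25 are distinguishable", {
  # oracle: overlap of two Gaussians evaluated on a dense grid
  x <- seq(440, 720, by = 0.1)
  g <- function(mu) exp(-0.5 * ((x - mu) / 25)^2)
  dense_cos <- spectral_cosine(g(520), g(580))
  lib <- make_spectral_library(peak_positions = c(A = 520, B = 580),
                               width_nm = 25)
  band_cos <- spectral_cosine(lib$endmembers[, "A"], lib$endmembers[, "B"])
  expect_lt(band_cos, 0.999)
  expect_equal(band_cos, dense_cos, tolerance = 0.02)
})

test_that("noiseless population lies exactly on the regression lines", {
  cfg <- noiseless_config(cells_per_roi = 100L,
                          resid_sd_N = 0, resid_sd_M = 0,
                          deficiency_fractions = zero_fractions())
  pop <- simulate_cell_population(cfg)
  lT <- log10(pop$cells$od_tomm20)
  expect_equal(log10(pop$cells$od_ndufb8),
               cfg$intercept_N + cfg$slope_N * lT, tolerance = 1e-12)
  expect_equal(log10(pop$cells$od_mtco1),
               cfg$intercept_M + cfg$slope_M * lT, tolerance = 1e-12)
})

test_that("planted phenotype counts obey the binomial bound", {
  n <- 10000L
  f <- zero_fractions()
  f$young_benign["ndufb8"] <- 0.2
  cfg <- sim_config(seed = 7L, groups = "young_benign",
                    n_patients_per_group = 1L, rois_per_patient = 1L,
                    cells_per_roi = n, stromal_fraction = 0,
                    deficiency_fractions = f,
                    image = image_config(height = 1664L, width = 1664L,
                                         noise_model = "none"))
  pop <- simulate_cell_population(cfg)
  got <- sum(pop$cells$phenotype == "ndufb8_deficient")
  expect_lt(abs(got - n * 0.2), 3 * sqrt(n * 0.2 * 0.8))
})

test_that("identical configuration gives identical output", {
  cfg <- noiseless_config(seed = 42L)
  p1 <- simulate_cell_population(cfg)
  p2 <- simulate_cell_population(cfg)
  expect_identical(p1$cells, p2$cells)
  lib <- make_spectral_library()
  cfg2 <- sim_config(seed = 42L, groups = "young_benign",
                     cells_per_roi = 20L,
                     n_patients_per_group = 1L, rois_per_patient = 1L,
                     image = image_config(height = 160L, width = 160L))
  q1 <- simulate_cell_population(cfg2)
  roi <- q1$cells
  t1 <- render_tissue_cube(roi, lib, cfg2)
  t2 <- render_tissue_cube(roi, lib, cfg2)
  expect_identical(t1$cube, t2$cube)
  expect_identical(t1$mask, t2$mask)
})

test_that("phenotype fractions summing above 1 are rejected", {
  f <- default_deficiency_fractions()
  f$tumour <- c(ndufb8 = 0.6, mtco1 = 0.4, high_tomm20 = 0.2)
  expect_error(sim_config(deficiency_fractions = f), "sum to more than 1")
})

test_that("deficient cells form spatial clones within an ROI", {
  f <- zero_fractions()
  f$young_benign["ndufb8"] <- 0.15
  cfg <- sim_config(seed = 3L, groups = "young_benign",
                    n_patients_per_group = 1L, rois_per_patient = 1L,
                    cells_per_roi = 200L, stromal_fraction = 0,
                    deficiency_fractions = f, clonal_cluster_size = 10,
                    image = image_config(height = 288L, width = 288L,
                                         noise_model = "none"))
  pop <- simulate_cell_population(cfg)
  d <- pop$cells[pop$cells$phenotype == "ndufb8_deficient", ]
  expect_gt(nrow(d), 10)
  # mean nearest-neighbour distance among deficient cells is far below that
  # of a random subset of the same size
  nn_dist <- function(sub, all_cells) {
    mean(vapply(seq_len(nrow(sub)), function(i) {
      dd <- sqrt((sub$cx[i] - sub$cx[-i])^2 + (sub$cy[i] - sub$cy[-i])^2)
      min(dd)
    }, 0))
  }
  set.seed(1)
  rand <- pop$cells[sample(nrow(pop$cells), nrow(d)), ]
  expect_lt(nn_dist(d), 0.7 * nn_dist(rand))
})

test_that("single-endmember cell renders as an exact multiple of its spectrum", {
  cfg <- noiseless_config(cells_per_roi = 1L)
  lib <- make_spectral_library()
  cell <- data.frame(patient_id = "P01", group = "young_benign",
                     roi_id = "P01_R01", region = "n/a", cell_id = "c1",
                     label = 1L, area_px = 0L, od_ndufb8 = 0, od_mtco1 = 0,
                     od_tomm20 = 2, od_ck = 0, od_dapi = 0,
                     tissue_class = "epithelial", phenotype = "normal",
                     cx = 80L, cy = 80L)
  tc <- render_tissue_cube(cell, lib, cfg)
  fg <- which(tc$mask == 1L, arr.ind = TRUE)
  spec <- tc$cube[fg[1, 1], fg[1, 2], ]
  expect_equal(spec, 2 * unname(lib$endmembers[, "Opal620"]),
               tolerance = 1e-12)
  # background with zero autofluorescence is exactly zero
  bg <- tc$cube[1, 1, ]
  expect_identical(max(abs(bg)), 0)
})

test_that("mask labels match the simulated cells one-to-one", {
  sc <- tiny_scene(cells_per_roi = 25L)
  labs <- sort(unique(sc$tc$mask[sc$tc$mask > 0]))
  expect_identical(labs, sort(sc$roi$label))
  # each centroid sits inside its own label
  expect_identical(sc$tc$mask[cbind(sc$roi$cy, sc$roi$cx)], sc$roi$label)
})

test_that("config YAML round-trips", {
  cfg <- sim_config(seed = 9L, cells_per_roi = 33L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$cells_per_roi, 33L)
  expect_equal(cfg2$deficiency_fractions, cfg$deficiency_fractions)
  expect_identical(simulate_cell_population(cfg)$cells,
                   simulate_cell_population(cfg2)$cells)
})
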