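# Segmentation, tissue classification and per-cell quantification.

fake_components <- function(planes, H = NULL, W = NULL) {
  H <- H %||% nrow(planes[[1]])
  W <- W %||% ncol(planes[[1]])
  out <- list(planes = planes, residual = matrix(0, H, W),
              markers = setdiff(names(planes), "autofluorescence"),
              wavelengths = NULL)
  class(out) <- "component_images"
  out
}

paint_disk <- function(mat, cy, cx, r, value) {
  d <- seq(-r, r)
  g <- expand.grid(dy = d, dx = d)
  g <- g[g$dy^2 + g$dx^2 <= r^2, ]
  mat[cbind(cy + g$dy, cx + g$dx)] <- value
  mat
}

test_that("well-separated cells segment one label per ground-truth centroid", {
  sc <- tiny_scene(seed = 2L, cells_per_roi = 10L)
  comp <- unmix_cube(sc$tc, sc$lib)
  mask <- segment_cells(comp)
  expect_equal(max(mask), 10L)
  hits <- mask[cbind(sc$roi$cy, sc$roi$cx)]
  expect_true(all(hits > 0))
  expect_equal(length(unique(hits)), 10L)
  # every label contains at least one nucleus pixel (DAPI-positive)
  dapi <- comp$planes[["DAPI"]]
  for (l in 1:10)
    expect_gt(max(dapi[mask == l]), 0)
})

test_that("blank DAPI yields an empty mask with a warning", {
  comp <- fake_components(list(DAPI = matrix(0, 32, 32),
                               Opal690 = matrix(0, 32, 32)))
  expect_warning(mask <- segment_cells(comp), "blank DAPI")
  expect_identical(max(mask), 0L)
})

test_that("touching nuclei separated by an intensity valley are split", {
  dapi <- matrix(0, 48, 48)
  # two disks whose footprints touch; the watershed must split them
  dapi <- paint_disk(dapi, 24, 18, 6, 10)
  dapi <- paint_disk(dapi, 24, 31, 6, 10)
  comp <- fake_components(list(DAPI = dapi, Opal690 = matrix(1, 48, 48)))
  mask <- segment_cells(comp, segment_params(dapi_sigma = 0.8,
                                             cyto_radius = 2L))
  expect_equal(max(mask), 2L)
  expect_true(mask[24, 18] != mask[24, 31])
  expect_true(all(mask[cbind(c(24, 24), c(18, 31))] > 0))
})

test_that("tissue classification separates simulated populations", {
  sc <- tiny_scene(seed = 4L, cells_per_roi = 60L)
  comp <- unmix_cube(sc$tc, sc$lib)
  ti <- classify_tissue(comp, sc$tc$mask)
  truth <- sc$roi$tissue_class[match(ti$label, sc$roi$label)]
  expect_gte(mean(ti$tissue_class == truth), 0.99)
})

test_that("tissue threshold boundary is strict and zero-ck cells are stromal", {
  ck <- matrix(0, 20, 20)
  ck[2:4, 2:4] <- 5            # cell 1: mean exactly 5
  mask <- matrix(0L, 20, 20)
  mask[2:4, 2:4] <- 1L
  mask[10:12, 10:12] <- 2L     # cell 2: zero ck
  comp <- fake_components(list(DAPI = matrix(1, 20, 20), Opal690 = ck))
  ti <- classify_tissue(comp, mask, threshold = 5)
  expect_identical(ti$tissue_class, c("stromal", "stromal"))
  ti2 <- classify_tissue(comp, mask, threshold = 4.999)
  expect_identical(ti2$tissue_class[1], "epithelial")
})

test_that("unimodal cytokeratin requires an explicit threshold", {
  set.seed(8)
  ck <- matrix(1 + 0.01 * runif(900), 30, 30)
  mask <- matrix(0L, 30, 30)
  for (i in 0:8) mask[(i %/% 3) * 9 + 2:4, (i %% 3) * 9 + 2:4] <- i + 1L
  comp <- fake_components(list(DAPI = matrix(1, 30, 30), Opal690 = ck))
  expect_error(classify_tissue(comp, mask), "unimodal")
  expect_silent(classify_tissue(comp, mask, threshold = 0.5))
})

test_that("quantification reproduces uniform abundances and geometry", {
  plane <- matrix(0, 16, 16)
  plane[3:6, 3:6] <- 2.5
  mask <- matrix(0L, 16, 16)
  mask[3:6, 3:6] <- 1L
  comp <- fake_components(list(DAPI = plane * 0, Opal520 = plane,
                               Opal570 = plane * 0, Opal620 = plane * 0,
                               Opal690 = plane * 0))
  q <- quantify_cells(comp, mask, list(patient_id = "P01",
                                       group = "young_benign",
                                       roi_id = "R01", region = "n/a"))
  expect_equal(q$od_ndufb8, 2.5)
  expect_equal(q$area_px, 16L)
  expect_equal(q$cx, mean(3:6) - 1)   # pixel-centred, origin top-left
  expect_equal(q$cy, mean(3:6) - 1)
  expect_false(q$edge)
})

test_that("noiseless quantification with ground-truth masks is exact", {
  sc <- tiny_scene(seed = 6L, cells_per_roi = 15L)
  comp <- unmix_cube(sc$tc, sc$lib)
  q <- quantify_cells(comp, sc$tc$mask,
                      sc$roi[1, c("patient_id", "group", "roi_id",
                                  "region")])
  m <- match(q$label, sc$roi$label)
  for (cn in c("od_ndufb8", "od_mtco1", "od_tomm20", "od_ck", "od_dapi"))
    expect_equal(q[[cn]], sc$roi[[cn]][m], tolerance = 1e-6)
})

test_that("border-touching cells are retained and flagged", {
  mask <- matrix(0L, 12, 12)
  mask[1:3, 5:7] <- 1L         # touches row 1
  mask[6:8, 5:7] <- 2L
  plane <- matrix(1, 12, 12)
  comp <- fake_components(list(DAPI = plane, Opal520 = plane,
                               Opal570 = plane, Opal620 = plane,
                               Opal690 = plane))
  expect_warning(
    q <- quantify_cells(comp, mask, list(roi_id = "R01")),
    "missing")
  expect_identical(q$edge, c(TRUE, FALSE))
  expect_identical(q$region, c("n/a", "n/a"))
})

test_that("segmentation recall and precision on the default scene", {
  cfg <- sim_config(seed = 10L, groups = "young_benign",
                    cells_per_roi = 100L,
                    n_patients_per_group = 1L, rois_per_patient = 1L)
  pop <- simulate_cell_population(cfg)
  lib <- make_spectral_library()
  tc <- render_tissue_cube(pop$cells, lib, cfg)
  comp <- unmix_cube(tc, lib)
  mask <- segment_cells(comp)
  hits <- mask[cbind(pop$cells$cy, pop$cells$cx)]
  recall <- length(unique(hits[hits > 0])) / nrow(pop$cells)
  precision <- length(unique(hits[hits > 0])) / max(mask)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})
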