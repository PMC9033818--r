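# Shared fixtures: small configurations and noiseless scenes.

`%||%` <- function(a, b) if (is.null(a)) b else a

# side length that fits n cells on the placement grid
image_side_for <- function(n, spacing = 16L, margin = 10L) {
  as.integer(ceiling(sqrt(n)) * spacing + 2L * margin)
}

# compact noiseless configuration for oracle tests; the image auto-scales
# to hold cells_per_roi
noiseless_config <- function(seed = 1L, cells_per_roi = 40L,
                             n_patients_per_group = 1L,
                             rois_per_patient = 1L, ...) {
  side <- max(160L, image_side_for(cells_per_roi))
  sim_config(seed = seed, cells_per_roi = cells_per_roi,
             n_patients_per_group = n_patients_per_group,
             rois_per_patient = rois_per_patient,
             image = image_config(height = side, width = side,
                                  noise_model = "none", af_level = 0),
             ...)
}

# zero phenotype fractions (pure control model)
zero_fractions <- function() {
  f <- default_deficiency_fractions()
  lapply(f, function(x) x * 0)
}

# one-ROI noiseless scene rendered from the default library
tiny_scene <- function(seed = 1L, cells_per_roi = 20L, ...) {
  cfg <- noiseless_config(seed = seed, cells_per_roi = cells_per_roi, ...)
  pop <- simulate_cell_population(cfg)
  lib <- make_spectral_library()
  roi <- pop$cells[pop$cells$roi_id == pop$cells$roi_id[1], , drop = FALSE]
  tc <- render_tissue_cube(roi, lib, cfg)
  list(cfg = cfg, pop = pop, lib = lib, roi = roi, tc = tc)
}

# exhaustive-subset NNLS oracle: minimise ||S x - y|| over x >= 0 by
# enumerating all support sets and keeping the best feasible solution
nnls_oracle <- function(S, y) {
  F <- ncol(S)
  best <- list(x = rep(0, F), rss = sum(y^2))
  for (m in seq_len(2^F - 1)) {
    sel <- as.logical(intToBits(m)[1:F])
    Ssub <- S[, sel, drop = FALSE]
    x <- tryCatch(qr.solve(Ssub, y), error = function(e) NULL)
    if (is.null(x) || any(x < -1e-10)) next
    x <- pmax(x, 0)
    rss <- sum((y - Ssub %*% x)^2)
    if (rss < best$rss - 1e-12) {
      full <- rep(0, F)
      full[sel] <- x
      best <- list(x = full, rss = rss)
    }
  }
  best$x
}
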