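Package: oxphosmif
Title: Single-Cell OXPHOS Deficiency Profiling from Multiplex Immunofluorescence
Version: 0.1.0
Authors@R:
    person("Prostate", "Mito Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for quantifying
    mitochondrial respiratory chain (OXPHOS) deficiency at single-cell
    resolution in multiplex immunofluorescence imaging of tissue sections.
    Includes a synthetic-data generator with known ground truth (cell
    populations, spectral libraries, multispectral image cubes), linear
    spectral unmixing by non-negative least squares with autofluorescence
    removal, DAPI/cytokeratin-based cell segmentation and per-cell
    quantification, control-cohort regression Z-scoring of NDUFB8 and MTCO1
    against TOMM20 with deficiency classification, cohort-level proportion
    and rank statistics, and reproducible visual outputs (MRC scatter
    graphs, pseudo-colour Z-score images, ROI heatmaps) each paired with a
    machine-readable twin table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
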