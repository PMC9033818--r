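---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oxphosmif)
```

This vignette is the package's own account of its science: the models it
implements, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the choices made where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The measurement model

A multispectral field is a cube $Y \in \mathbb{R}^{H\times W\times B}$
with $B = 15$ bands on the 440–720 nm grid (20 nm steps). The physical
model at each pixel is linear:

$$y(\lambda) = \sum_f a_f\, S_f(\lambda) + a_{\mathrm{af}}\,
S_{\mathrm{af}}(\lambda) + \varepsilon(\lambda),$$

where $S_f$ are fluorophore emission spectra (DAPI, Opal520, Opal570,
Opal620, Opal690; unit peak), $S_{\mathrm{af}}$ is a broad tissue
autofluorescence spectrum, $a_f \ge 0$ are abundances, and $\varepsilon$
is camera noise. Unmixing solves, per pixel, a nonnegativity-constrained
least-squares fit against all endmembers *plus* autofluorescence
(Lawson–Hanson active set, `src/nnls.cpp`). Estimating autofluorescence
jointly and then discarding its plane is how its contribution is removed;
we chose joint estimation over sequential subtraction because it is more
stable and never produces negative marker signal. The commercial software
used in the original acquisition protocol does not disclose its algorithm;
we document our choice rather than claim equivalence.

Because library spectra are unit-peak normalised, abundances carry the
cube's intensity units. Absolute units cancel in Z-scoring, which is the
only place marker values are compared.

Library estimation from single-stain references (`build_library_from_
singleplex`) takes the mean spectrum of the brightest 2 % of pixels (by
total band sum), subtracts the autofluorescence reference (mean spectrum
of the unstained cube), clips negatives and renormalises. The 2 % default
is a declared choice; the protocol we follow says only that representative
single-stained images are used.

## 2. The control-cohort Z-score model

On epithelial cells from the control cohort (benign tissue, patients under
45), with $T, N, M$ the log10 per-cell mean intensities of TOMM20, NDUFB8
and MTCO1:

* $\hat\mu_T, \hat\sigma_T$: sample mean/SD of $T$;
* OLS: $N = a_N + b_N T + \varepsilon_N$ and $M = a_M + b_M T +
  \varepsilon_M$, residual SDs $\hat\sigma_N, \hat\sigma_M$ with the
  $n-2$ denominator (unbiased residual variance; the source protocol is
  silent, and self-scored controls then have z SD
  $\sqrt{(n-1)/(n-2)} \approx 1$).

Z-scores: $z_T = (T-\hat\mu_T)/\hat\sigma_T$ and
$z_N = (N - a_N - b_N T)/\hat\sigma_N$ (likewise $z_M$), i.e. NDUFB8 and
MTCO1 are normalised for mitochondrial mass through the regression
expectation, not by a ratio.

**Categories.** The verbal definitions "very low ($z<-6$)" and "low
($z<-3$)" overlap; the only partition consistent with both is precedence
to *very_low*, so *low* means $[-6,-3)$. *Normal* is closed
($[-3,3]$; $[-2,2]$ for TOMM20) and deficiency is strict $z<-3$, so a
cell at exactly $-3$ is normal and not deficient. An exhaustive boundary
sweep at $\pm\{0,2,3,6\}\pm10^{-9}$ pins this down in the tests.

**Nonpositive intensities** cannot be log-transformed. The default policy
drops such cells and reports the count; flooring at a configurable
$\varepsilon$ is available but not default, because it fabricates a value
where the measurement failed. One pooled control model is fitted across
all control patients (matching the pooled-cohort procedure); the model is
YAML-serialisable so per-batch use remains possible.

## 3. The synthetic cohort generator

The generator is the exact inverse of the fitting procedure — Gaussian
$T$, linear $N,M$ on $T$ with Gaussian residuals — so parameter-recovery
and self-scoring tests have sharp expectations. Its defaults are the
stated world of the package and are not tuned:

| parameter | default | rationale |
| --- | --- | --- |
| `mu_T`, `sd_T` | 2.0, 0.2 | arbitrary intensity scale; study values unreported |
| `intercept_N`, `slope_N`, `resid_sd_N` | 0.5, 0.9, 0.05 | worked-example values used throughout the tests |
| `intercept_M`, `slope_M`, `resid_sd_M` | 0.3, 0.95, 0.06 | same order as NDUFB8, slightly noisier |
| `deficiency_shift` | 5 residual SDs | planted deficits map 1:1 onto the $z<-3$ rule ($\Phi(2)\approx0.977$ sensitivity) |
| `high_tomm20_shift` | 3 × `sd_T` | clears the $z_T>2$ cut |
| `deficiency_fractions` | published cohort percentages (young 0.23/0.277/0.82 %; aged benign 0.61/4.52/4.26 %; tumour 15.68/1.38/11.87 %; benign-adjacent 0.059/0.16/6.49 %) | the cohort frequencies the method reported |
| `clonal_cluster_size` | 10 cells | deficiency emerges clonally; size unreported, chosen once |
| `stromal_fraction` | 0.25 | exercises tissue classification |
| cytokeratin log10 means | 1.0 (epithelial) vs −1.0 (stromal) | ≥10-fold separation so the automatic split is well-posed |
| image | 288 px, nucleus r=3, cytoplasm r=6, spacing 16 | ~200 cells per 20× field, mostly touching-free |
| noise | Poisson shot (gain 100) + Gaussian read (SD 0.01) | standard fluorescence camera model; acquisition noise unreported |

Deficient cells are planted in spatially contiguous clones (a clone seeds
at a random cell and absorbs its nearest unassigned neighbours; sizes
$1+\mathrm{Pois}(\text{mean}-1)$), giving the pseudo-images and heatmaps
genuine spatial structure. High-TOMM20 cells are placed at random — no
clonality is claimed for them. Phenotypes are mutually exclusive by
construction; the `combined` label is reserved but unused by default
because multiple simultaneous alterations were reported as rare.

Rendering stamps each cell's markers uniformly over a circular
cytoplasmic footprint; DAPI is painted on the nuclear disk with its
amplitude scaled so the *footprint mean* equals the cell's nominal DAPI
value (per-cell means are then exactly the planted abundances — the basis
of the `1e-6` quantification oracle). Noise streams are seeded from the
configuration seed plus an ROI-id hash, so identical configurations give
byte-identical cubes while different ROIs get independent noise.

**What a green test does not establish.** The generator has no staining
chemistry, no TSA amplification kinetics, no spatial autofluorescence
texture (autofluorescence is uniform), no out-of-focus light, no
irregular cell shapes and no 3-D structure. Segmentation scores
(recall/precision ≥ 0.95) therefore certify the algorithm on
well-separated synthetic cells, not on real tissue. The statistical
stages accept ground-truth masks precisely so their validation does not
depend on the segmenter.

## 4. Segmentation and quantification

Nuclei: Gaussian blur (σ = 1 px) of the DAPI plane, Otsu threshold
(plateau ties resolved at the plateau midpoint, which places the cut in
the empty gap of a bimodal histogram), speck removal (< 4 px), exact
Euclidean distance transform, local-maximum markers, watershed flood.
Cytoplasm: each nucleus grows 4 px outward (one 4-connected ring per
round), stopping at neighbouring cells — ties to the lowest label, a
deterministic precedence — and optionally constrained to
cytokeratin-positive support. Every label contains its nucleus by
construction. These parameters replace an undisclosed proprietary
trainable segmenter; they are declared, not inferred. Edge-touching cells
are kept and flagged `edge` so either analysis policy is possible
downstream. Per-cell values are **means** over the footprint (matching
the mean-signal-intensity convention), coordinates are pixel-centred with
the origin at the top-left pixel, x rightward, y downward.

Tissue classification is a per-cell threshold on mean cytokeratin,
automatic via Otsu on log10 means (intensities are log-normal); if the
two classes differ by less than twofold the distribution is treated as
unimodal and an explicit threshold is required — silently accepting an
arbitrary cut on a unimodal histogram would classify noise. The boundary
is strict: a cell exactly at the threshold is stromal.

## 5. Cohort statistics

Group proportions are pooled over cells (not means of patient
proportions), consistent with cohort-level cell counts; patient-stratified
summaries are also emitted. The chi-square test is Pearson's without
continuity correction, and no multiple-testing adjustment is applied —
raw p-values are reported, matching the original analysis; expected
counts below 5 set a warning flag. Percentage-point differences are
computed from unrounded operands and rounded to two decimals at
reporting. Two published Δ values (4.25 and 15.44) differ by 0.01 from
the difference of their printed operands, indicating rounding before
subtraction upstream; this package subtracts first (its `t1`/`t3`
acceptance values are 4.24 and 15.45).

ROI-level comparisons use the unweighted mean Z-score of valid epithelial
cells per ROI; the Kruskal–Wallis H statistic uses the tie-corrected form
with a $\chi^2_{k-1}$ approximation.

## 6. Reporting

Every figure writes a machine-readable twin (CSV of exactly the plotted
values); the test suite asserts on twins and never on pixels, so figures
are reproducible but not load-bearing. MRC graphs plot $z_N$ against
$z_M$ with spot radius $\propto \sqrt{\text{area}}$ — spot *area*
proportional to cell area, the only scale-free reading of "size
correlates with area". Pseudo-colour images map z through a diverging
blue–white–red scale clipped at ±6 (aligned with the *very_low*
threshold) over a neutral background; cells missing from the score table
get a grey "missing" colour plus a warning. Heatmaps are the ROI × marker
matrix of mean Z-scores, sortable by a marker and by group. Exact colour
scales and axis limits of the original figures are not published;
defaults here are declared, not reproductions.

## 7. Numerical and environment notes

* NNLS tolerance $10^{-10}$, ≤ 200 active-set iterations; noiseless
  synthetic cubes unmix to ≤ $10^{-6}$ abundance error and ≤ $10^{-9}$
  residual (tested).
* TIFF I/O is a minimal baseline implementation (little-endian,
  uncompressed, float32/int32 pages, wavelength in ImageDescription),
  present because no R TIFF reader is available in the target
  environment; it is cross-validated against an independent Python
  reader in the tests.
* Degenerate inputs fail loudly: zero residual SD (collinear controls),
  rank-deficient libraries (the collinear pair is named), zero marginals
  in contingency tables, blank DAPI planes (empty mask + warning).
* All randomness flows from the configuration seed; rendering derives a
  per-ROI stream. Test and acceptance sizes follow the stated criteria
  (e.g. 5 000 control cells for parameter recovery, 100 000 for the
  $\Phi(-3)$ null check, 2 000 replicates for chi-square calibration).

## 8. Known limitations

Uniform autofluorescence and circular cells make unmixing and
segmentation easier than on real tissue; no crosstalk beyond linear
mixing is modelled; no hierarchical modelling of patient clustering (by
design — proportions are compared at the cell level, as in the original
analysis); the proprietary `.im3`/`.qptiff` formats and the commercial
segmenter's project files are out of scope.
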