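---
title: "Methods: nest-margin spatial analysis of lymphocyte aggregates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nest-margin spatial analysis of lymphocyte aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestmargin)
```

## The problem

Tumor-infiltrating lymphocytes (TILs) carry prognostic information in
many solid tumors, and *where* they sit matters: lymphocytes in direct
contact with tumor cells (intratumoral TILs) behave differently from
those in the stroma between tumor-cell nests. Manual TIL scoring is slow
and subjective, and intratumoral TILs in particular are hard to score by
eye because of their low abundance and patchy distribution.

`nestmargin` implements an automated pipeline for
haematoxylin-and-eosin (H&E) slide images: the slide region is cut into
nonoverlapping square patches (128 µm, i.e. 512 px at 40×
magnification), each patch is categorized as *tumor*, *lymphocyte
aggregate*, or *other*, tumor-cell nests are detected as dense clusters
of tumor patches on the lattice, and the tissue is partitioned into the
nest interior, the nest border (internal + external margin), and the
outside. Twelve spatial indicators — the percentage of each category
overall and within each region — summarize a subject, and survival
analysis relates them to outcome. The headline quantity is
`Lymph_inside%`: the share of nest-interior tissue occupied by
lymphocyte aggregates, an automated analogue of intratumoral TIL
density.

## Patch grid and labeling

A patch is **tumor-flagged** if it contains ≥ 20 tumor cells and
**lymph-flagged** if it contains ≥ 20 lymphocytes; the flags are
independent, and a patch may carry both (lymphocytes do infiltrate tumor
nests). Quality control is saturation-based: a pixel counts as tissue
when its HSV saturation exceeds 0.07 (stained tissue is colored, glass
is near-white), and a patch passes when at least 25% of its pixels are
tissue. Both thresholds are configurable; saturation thresholding is the
standard white-background rejection for H&E and the exact criterion is a
package choice, as no single convention dominates.

The three-way category used by the indicators needs a precedence rule
for dual-flagged patches. We categorize **lymph over tumor over
other**: a dual-flagged patch counts as a lymphocyte-aggregate patch.
The rationale is that the motivating quantity is intranest lymphoid
infiltration — folding dual-flagged patches into *tumor* would erase
exactly the signal `Lymph_inside%` is built to capture. Nest detection
is unaffected by this choice because it always uses the raw tumor flag.
This is a declared convention: the categories must be mutually
exclusive for the per-region triples to sum to 100%, and the precedence
direction is the one that preserves the infiltration signal.

Partial edge strips of an image are dropped rather than padded, so every
patch has the same physical footprint.

## The patch classifiers

Two independent binary CNNs (tumor vs rest, lymphocyte aggregate vs
rest) share one VGG-style architecture: four 3×3 same-padded
convolutions with 32, 32, 64, 64 filters, each followed by ReLU and 2×2
max pooling; then flatten, a 512-unit ReLU dense layer, dropout, and a
2-unit softmax output. With 512×512×3 input the flatten layer has
32·32·64 = 65,536 units and the parameter counts are 896 / 9,248 /
18,496 / 36,928 (convolutions), 33,554,944 and 1,026 (dense), 33,621,538
total — all computed by closed form in `build_model()`, so the
architecture is checkable without training. Same padding is forced by
that arithmetic: only pooling may change the spatial size, or the
flatten length would not come out at 65,536.

The network is implemented natively in this package: convolutions are
evaluated as im2col gathers followed by a single BLAS matrix product,
and gradients are exact analytic backpropagation, verified against
finite differences in the test suite (worst relative error ~1e-6).
Training uses Adam (default learning rate 1e-4, configurable; the test
fixtures use 1e-3 for speed), dropout 0.5, a stratified 8:2
train/validation split, and optional early stopping on validation loss.
These optimizer settings are standard VGG-style defaults; nothing in
the pipeline depends on them beyond reaching a separating solution on
the fixture.

`evaluate_roc()` computes the AUC as the Mann–Whitney statistic from
ranks (ties count one half) and its confidence interval by the DeLong
placement-value variance, with a seeded stratified bootstrap as an
alternative. `grad_cam()` explains a prediction as the ReLU-rectified,
gradient-weighted sum of the last convolutional layer's feature maps;
the native heatmap is input/8 per side (64×64 at 512 px, since the last
convolution sits after three of the four poolings) and is
nearest-neighbor upsampled for overlay.

## Nest detection and margins

Tumor nests are found by DBSCAN on the patch lattice with the package's
defaults `radius = 2` and `min_neighborhood_size = 4`. The radius is in
**patch-index units** with Euclidean distance, so the neighborhood is
the 12 offsets with `dr² + dc² ≤ 4`; the analysis object is the patch
grid, which makes patch units the natural scale. A tumor patch is a
core patch when ≥ 4 *other* tumor patches lie within the radius
(self excluded); clusters are connected components of core patches plus
density-reachable non-core tumor patches, which join the nearest core's
cluster with ties broken toward the lowest cluster id — a deterministic
DBSCAN convention. Isolated tumor patches are noise: they form no nest
and fall in the *outside* region.

Margins use 8-connectivity (diagonal contact is physical contact at
patch scale; 4-connectivity is available):

* **internal margin** — clustered patches with ≥ 1 non-clustered tissue
  neighbor;
* **external margin** — non-clustered tissue patches with ≥ 1 clustered
  neighbor;
* **inside** — clustered patches minus the internal margin;
* **outside** — everything else on tissue.

Out-of-grid cells and QC-failed patches never count as neighbors, so a
nest flush against the slide edge has no margin on that side, and
non-tissue patches enter no region and no denominator. The *border*
indicators pool the internal and external margins into one region,
giving a single Tumor/Lymph/Other border triple.

Each indicator is `100 · (patches of category X in region r) / (tissue
patches in region r)`; a region with zero patches yields a missing
value, never zero — a slide without detected nests genuinely has no
inside compartment, and coding it 0% would fabricate a measurement.
Downstream survival analysis drops missing values listwise.

## Survival analysis

Kaplan–Meier curves, the two-group log-rank test, and Cox regression
(Efron tie handling, Wald intervals) are delegated to the `survival`
package behind this package's interfaces and are verified against hand
tabulations in the tests. `optimal_cutpoint()` implements minimum-p
dichotomization: candidate cutpoints are midpoints between consecutive
distinct indicator values whose splits leave at least
`ceiling(minprop · n)` subjects on each side (`minprop = 0.1`, the
common default of the cutpoint-selection tools this mirrors), the
log-rank p is computed for every candidate, and the smallest-p split is
returned, ties broken toward the smaller cutpoint.

The minimum of many correlated log-rank tests is **not** a valid
p-value; the package documents and tests this anticonservatism (under
the null the naive procedure rejects far more than 5% of the time). An
optional corrected p-value (the improved-Bonferroni approximation for
the supremum of a standardized Brownian bridge over the admissible
quantile range) is available via `corrected = TRUE` but off by default,
because the primary output mirrors the uncorrected convention of the
tools this reimplements. Multivariable Cox models enter indicators
continuously by default (per-fraction scale), with dichotomized entry
available through the cutpoint result; confounders such as age, sex,
and stage are passed as ordinary covariates.

Non-convergence and monotone-likelihood separation are flagged on the
result object rather than silently reported.

## The synthetic-data generator

The generator exists so every downstream stage is testable with no
slide archive. It emulates three things:

1. **Label grids** — `n_nests` connected tumor blobs (a lattice disk
   dilated by a short random walk, giving irregular but connected
   shapes like carcinoma nests), with lymph flags drawn independently
   per tissue patch at region-specific rates `p_lymph_inside`,
   `p_lymph_border`, `p_lymph_outside`. The generator's own
   ground-truth *border* is the one-patch band on either side of the
   nest boundary, mirroring the internal + external margin definition,
   and is retained for validation against the spatial module.
2. **Patch images** — eosin-pink background with dark-stained nuclei;
   tumor nuclei are strictly larger than lymphocyte nuclei, so the two
   classes are morphologically separable by construction, and nucleus
   counts respect the 20-cell labeling rule. This is deliberately
   minimal: no stain variation, scanner artifacts, stromal texture, or
   overlapping-nucleus clutter. A classifier that separates this
   fixture demonstrates that the training/evaluation machinery works,
   not that it would reach any particular accuracy on real H&E.
3. **Survival** — exponential event times under a proportional-hazards
   model `h(t|z) = baseline_rate · exp(beta · z)` driven by a chosen
   indicator on the fraction scale, with independent exponential
   censoring truncated administratively at `max_followup`. Defaults
   (`baseline_rate = 0.1`, `censor_rate = 0.05`, `max_followup = 60`)
   give a cohort with roughly one-third observed events over a
   five-year-like window, a realistic yield for a bladder-cancer
   cohort. Cohorts draw each subject's three infiltration
   probabilities uniformly on [0, 0.8], producing wide indicator spread
   across subjects; nest geometry is held at the template
   configuration, so tumor-fraction indicators vary less than
   lymphocyte indicators by design.

Nest counts and sizes per slide are free parameters, not estimates of
any real distribution; defaults (48×48 grids, 3 nests of radius 4–8)
were fixed once as a plausible mid-density tissue and are not tuned.

All generators are deterministic given their seed and restore the
caller's RNG state.

## Numerical and design notes

* Grids are 0-based, row-major; pixel origins are half-open intervals.
* Category triples sum to 100 exactly (up to floating-point rounding on
  the order of 1e-13) because categories are mutually exclusive.
* Parameter-recovery simulations in the tests state their own follow-up
  conditions: estimator checks (e.g. recovering β = −3, or a null β = 0
  with a standardized covariate) run under near-complete observation so
  that sampling error, not censoring, drives the comparison, while
  pipeline-level direction checks use the default censoring above.
* Problem sizes used by the test suite and acceptance script — 2,000
  training images at 32 px for the classifier fixture, 100 random grids
  up to 20×20 for the clustering oracle, cohorts of 200 subjects on
  48×48 grids over 20 replicates for the direction check, 50 replicates
  at n = 500 for the Cox recovery checks — were chosen as the smallest
  sizes at which each property is statistically decisive.
* The CNN trains at reduced input sizes (any multiple of 16); the
  architecture arithmetic is always checked at the canonical 512 px.

## Limitations

* Proprietary pyramidal WSI formats are out of scope; input is
  PNG/TIFF or a pre-labeled patch table.
* No stain normalization or nucleus segmentation of real images: the
  20-cell rule is applied from provided counts or from the generator's
  ground truth.
* The min-p cutpoint's uncorrected p-value is anticonservative (by
  construction and by test); use `corrected = TRUE` for honest
  inference on a single indicator.
* Margin geometry is patch-resolution: no polygonal hulls or
  distance-to-margin gradients.

## A worked run

```{r example, eval = FALSE}
cfg <- pipeline_config(out_dir = "run1", seed = 1, n_subjects = 20)
manifest <- run_pipeline(cfg)

ind <- read.csv(file.path("run1", "indicators.csv"))
res <- read.csv(file.path("run1", "survival_results.csv"))
subset(res, indicator == "Lymph_inside")
```

The manifest records every parameter with a fixed pipeline value
(128 µm patches, 20-cell rule, radius 2, min_neighborhood_size 4, 8:2
split) along with seeds and output checksums, and reruns with the same
config are bit-identical.
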