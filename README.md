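# nestmargin

Spatial analysis of tumor-cell nests and lymphocyte aggregates on
H&E patch grids, with survival analysis of the resulting indicators.

## What it does and who it is for

In solid tumors such as muscle-invasive bladder cancer, the *location*
of lymphocyte aggregates relative to tumor-cell nests — inside a nest,
at its margin, or in the surrounding stroma — carries prognostic
information that overall lymphocyte density misses. `nestmargin` is for
computational-pathology researchers who want an automated, testable
version of that analysis:

1. **Tile** a slide image into nonoverlapping 128 µm patches (512 px at
   40×) with saturation-based quality control, and label patches by the
   ≥ 20-cell rule (≥ 20 tumor cells → tumor patch, ≥ 20 lymphocytes →
   lymph patch, overlap permitted).
2. **Classify** patches with twin binary VGG-style CNNs (tumor vs rest,
   lymphocyte aggregate vs rest), implemented natively in R, with
   Grad-CAM explanations.
3. **Detect nests** by density-based clustering on the patch lattice
   (DBSCAN, Euclidean patch-index distance, `radius = 2`,
   `min_neighborhood_size = 4`) and delineate the internal/external
   margins.
4. **Quantify** the 12 spatial indicators: Tumor/Lymph/Other
   percentages overall and in the *inside*, *border*, and *outside*
   regions, e.g.

   `Lymph_inside% = 100 · #(lymph patches inside nests) / #(tissue patches inside nests)`

5. **Relate to outcome** via minimum-p log-rank cutpoints
   (`minprop = 0.1`), Kaplan–Meier curves, and Cox proportional-hazards
   regression (Efron ties), `h(t | z) = h0(t) · exp(βz)`.

A synthetic-data module generates label grids with known nest geometry
and infiltration rates, morphologically separable patch images, and
proportional-hazards survival data, so the entire pipeline runs and is
tested without any slide archive.

## Worked example

Simulate a 40-subject cohort, compute indicators, and test each
indicator against survival:

```r
library(nestmargin)

cfg <- pipeline_config(out_dir = "run1", seed = 1, n_subjects = 40)
run_pipeline(cfg)

ind <- read.csv("run1/indicators.csv")
head(ind[, c("subject_id", "Tumor", "Lymph", "Other", "Lymph_inside")], 4)
#>   subject_id  Tumor Lymph Other Lymph_inside
#> 1       S001  5.903 29.95 64.15        33.94
#> 2       S002  6.076 67.49 26.43        57.23
#> 3       S003  7.378 36.15 56.47        31.51
#> 4       S004 10.590 52.26 37.15        21.23

res <- read.csv("run1/survival_results.csv")
subset(res, indicator == "Lymph_inside")
#>      indicator  n cutpoint logrank_p     hr   cox_p
#> 5 Lymph_inside 40     29.1    0.0011 0.0152 0.00914
```

Each row dichotomizes one indicator at its minimum-p log-rank cutpoint
and fits a continuous Cox model on the fraction scale. Here the cohort
was simulated with a protective `Lymph_inside%` effect (β = −3 per unit
fraction), and the pipeline recovers it: subjects above 29.1% intranest
lymphocyte coverage survive longer (log-rank p = 0.0011), and the
continuous hazard ratio 0.0152 ≈ exp(−4.2) per unit fraction is
protective (Cox p = 0.009). The same objects are available
programmatically:

```r
d  <- merge(ind, read.csv("run1/survival.csv"), by = "subject_id")
optimal_cutpoint(d$time, d$event, d$Lymph_inside)
#> min-p cutpoint 29.07 (chisq 10.651, p 0.0011; 15 low / 25 high, minprop 0.10)

m <- build_model()        # canonical CNN at 512 x 512 x 3
attr(m, "total_params")
#> [1] 33621538
```

The architecture arithmetic is exact: convolution layers carry 896,
9,248, 18,496, and 36,928 parameters, the dense layers 33,554,944 and
1,026, for 33,621,538 total.

## Scope

Proprietary pyramidal slide formats, stain normalization, nucleus
segmentation of real images, and cell-resolution margin geometry are
out of scope; see the methods vignette
(`vignettes/nestmargin-methods.Rmd`) for the model, parameter, and
design details.
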