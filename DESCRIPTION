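Package: nestmargin
Title: Spatial Analysis of Tumor Nests and Lymphocyte Aggregates on
    Histology Patch Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An automated pipeline for quantifying the spatial
    distribution of lymphocyte aggregates relative to tumor-cell nests on
    haematoxylin-and-eosin patch grids. Tiles slide images into
    nonoverlapping 128-micron patches with saturation-based quality
    control, labels patches by cell content (>= 20 tumor cells or >= 20
    lymphocytes), trains twin binary convolutional classifiers with
    Grad-CAM explanations, detects tumor-nest clusters and their
    internal/external margins by density-based clustering on the patch
    lattice, computes twelve region-wise spatial indicators (tumor /
    lymphocyte / other percentages overall and inside, at the border of,
    and outside nests), and relates the indicators to patient outcome via
    minimum-p log-rank cutpoints, Kaplan-Meier curves, and Cox
    regression. A synthetic-data module generates label grids, patch
    images, and proportional-hazards survival data so the whole pipeline
    is testable without slide archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    survival,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
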