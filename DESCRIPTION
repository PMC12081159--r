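Package: histotile
Title: Reliability-Guided Filtering and Memory-Cell Tile Classification
    for Histopathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for tile-based analysis of prostate histopathology
    images. Provides reliability-guided ordered filtering of degraded
    images by geodesic confidence propagation, color correlogram and
    autocorrelogram descriptors, a nonlocal patch-graph Laplacian
    spectral basis with manifold-space contrast adjustment, and an
    immune-inspired memory-cell nearest-prototype classifier with ROC/AUC
    evaluation and per-tile score heatmaps. Includes a seeded generator
    of synthetic tissue-like images so every stage is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
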