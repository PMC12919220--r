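Package: geotaxr
Title: Automated Analysis of Drosophila Negative-Geotaxis Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end analysis of tap-and-climb (negative geotaxis) assay
    recordings of Drosophila in multi-vial racks: motion-energy segmentation
    of recordings into per-tap trials, vial localisation with
    intersection-over-union evaluation, per-frame fly centroid tracking with
    low/middle/high performer zoning, conversion to physical units,
    sex-split aggregation of climbing height, velocity and zone occupancy
    across replicates, and a statistical layer combining linear mixed-effects
    models (Wald tests, harmonic-mean p-value combination) with time-resolved
    and peak Mann-Whitney U tests. Includes a synthetic scene generator that
    renders climbing-fly recordings with ground-truth boxes and trajectories
    so the whole pipeline is testable without laboratory video.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    lme4,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
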