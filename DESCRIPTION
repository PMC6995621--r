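Package: soleVision
Title: Biomass Estimation of Flatfish from Top-View Tank Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An artificial-vision pipeline that estimates per-fish and
    per-tank biomass of benthic flatfish (Senegalese sole) from a single
    top-view tank photograph. The pipeline normalizes image size, segments
    fish and a circular reference object of known diameter, self-calibrates
    the metric scale from the reference, measures each fish body length and
    width with a minimum-area rotated rectangle, and predicts individual
    weight with a nine-layer feed-forward network trained on morphometric
    records (with a closed-form allometric baseline as oracle and fallback).
    Includes a synthetic scene and cohort generator with exact ground truth,
    detection-evaluation utilities, and before/after growth statistics
    (paired and Welch t-tests, group summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    tiff,
    jpeg,
    optparse
Config/testthat/edition: 3
biocViews: Software, Visualization, Classification, Regression
RoxygenNote: 7.3.3
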