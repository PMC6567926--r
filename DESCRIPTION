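Package: airspacer
Title: Airspace Quantification in High-Resolution Lung CT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and counts gas-filled airspaces in high-resolution
    (synchrotron-grade) lung CT slice stacks using multi-scale morphological
    top-hat segmentation and regional-minima peak counting; partitions each
    slice into depth-based concentric regions (subpleural, mantellar, core);
    computes airspace density (ASden, units per mm^3) and mean airspace
    surface extension (ASext, voxels); and provides the accompanying
    statistical layer (per-region linear regression of the metrics on PEEP,
    extra-sum-of-squares F comparison of regression lines, exact paired
    Wilcoxon signed-rank tests with multiplicity-corrected alpha). A
    stochastic critical-closing-pressure phantom generator produces synthetic
    slice stacks with ground truth, so the whole pipeline can be validated
    end-to-end without access to raw imaging data. Single-distance phase
    retrieval is included as an optional preprocessing step for
    propagation-based phase-contrast acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
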