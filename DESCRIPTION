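Package: thermalign
Title: Cascaded Shape Regression for Face Alignment in Thermal Infrared Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Facial-landmark alignment for thermal infrared imagery using
    cascaded shape regression with gradient-boosted ensembles of regression
    trees on shape-indexed two-pixel intensity-difference features. Provides
    readers and writers for thermal frames (plain-matrix CSV, 16-bit TIFF,
    8-bit PNG), iBUG-style 68-point landmark files and dataset manifests;
    mean-shape initialization from face bounding boxes; horizontal-flip
    augmentation with left/right landmark reindexing; subject-wise k-fold
    cross-validation; the normalized point-to-point error (NPPE) metric with
    cumulative error distribution curves and per-distance summaries; and a
    synthetic thermal-face generator emulating a multi-subject, multi-distance,
    multi-pose acquisition protocol so the full pipeline runs with no external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    png,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
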