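Package: icdetect
Title: Invasive Carcinoma Detection on Breast Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Remi", "Fournier", email = "remi.fournier@example.org", role = c("aut", "cre"))
Description: A patch-based pipeline that detects and locates invasive
    carcinoma (IC) on breast whole-slide images (WSI). The pipeline filters
    epithelial nuclear regions with fast non-learned image-processing
    criteria, parses them into 256x256 patches at zoom x20, scores each
    patch from its same-center x5 context image with a convolutional
    feature extractor topped by a random-forest head, and aggregates patch
    scores into a slide-level IC score with F1-maximizing operating points.
    A two-phase master/calibrated transfer-learning protocol adapts the
    classifier to a new acquisition center from a small amount of target
    data. A parametric synthetic-slide generator (pyramidal slides, labeled
    ROIs, per-center stain styles) makes every stage testable without any
    real WSI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
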