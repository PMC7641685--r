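Package: mammocheat
Title: Cheat-Sheet Attribute Encoding and CNN Classification of Mammograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for binary (malignant versus
    non-malignant) classification of mediolateral-oblique mammograms with a
    small convolutional neural network aided by a "cheat sheet": classical
    attributes (an electronic-biopsy mean intensity and the region-of-interest
    radius) encoded as two uniform 10-pixel frames drawn around the ROI before
    classification. Includes MIAS-style PGM input/output, automatic ROI
    extraction (side detection, artifact and pectoral-muscle removal, bounding
    rectangle, genetic-algorithm refinement over height, width and intensity
    cut-off genes), rotation-based training-set augmentation, a compact CNN
    implemented with RcppArmadillo, confusion-matrix and ROC/AUOC evaluation, a
    four-arm experiment harness (original, augmented, cheat-sheet, both), and
    the statistical analysis of a packaged 15-run MIAS benchmark table
    (per-arm summaries, one-sided variance-ratio and mean-difference
    confidence bounds). A synthetic phantom generator provides ground-truthed
    MLO-like images so the whole pipeline is testable without the MIAS
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
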