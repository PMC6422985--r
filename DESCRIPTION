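Package: fetalrp
Title: Fetal Hypoxia Screening from Cardiotocograms with Recurrence Plots
    and a Compact Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns intrapartum fetal heart rate (FHR) traces into
    recurrence-plot images and classifies them as normal or pathological
    (hypoxia, umbilical-artery pH below 7.15). Provides a synthetic
    cardiotocography generator, rule-based FHR preprocessing (dropout
    splicing and interpolation, adjacent-jump stabilisation, Hermite range
    repair), time-delay embedding with per-point k-nearest-neighbour
    recurrence thresholds, parameter-grid image augmentation, a compact
    8-layer convolutional classifier trained with Adam, and 10-fold
    cross-validated evaluation with confusion-matrix metrics and ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
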