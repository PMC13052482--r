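Package: phasorboost
Title: Phasor-Based Autofluorescence Lifetime Features and Ensemble
    Classification of Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fit-free analysis of time-correlated single photon
    counting (TCSPC) autofluorescence decays and supervised classification of
    benign versus malignant tissue. Implements the phasor transform with
    instrument-response-function referencing, phase and modulation lifetimes,
    fractional channel intensities and the optical redox ratio; quality-control
    filtering of low-count decays; region-of-interest feature extraction into a
    26-parameter observation table with named ablation sub-pools; an
    AdaBoost.M1 ensemble of depth-limited decision trees with stratified
    cross-validation and a seeded hyperparameter search; evaluation metrics
    (sensitivity, specificity, accuracy, PPV, NPV, MCC, ROC/AUC) with repeated
    run aggregation and predictor importance; probability-of-malignancy maps
    from sequential single-point predictions; and a synthetic multichannel
    fiber-probe TCSPC scan generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
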