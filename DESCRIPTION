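Package: vfshock
Title: Predicting Defibrillation Success from Pre-Shock Ventricular
    Fibrillation Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and machine-learning pipeline for predicting
    whether a defibrillation countershock will restore spontaneous circulation,
    from a short pre-shock ventricular fibrillation ECG segment and, optionally,
    a capnography (PetCO2) trace. Implements Savitzky-Golay preprocessing with
    iterative baseline-jump removal, a pole-count time-series feature, dual-tree
    complex wavelet band statistics, recurrence period density prototype
    distances (RPD-PD) with separation-maximizing parameter selection, an
    amplitude spectrum area (AMSA) baseline with a decision-stump threshold, and
    cost-sensitive recursive-feature-elimination SVM classification evaluated by
    twice-nested cross-validation. A seeded generator of two-class VF-like
    signals supports end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
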