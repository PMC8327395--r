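Package: gazenav
Title: Detecting Moments of Navigation Loss from Eye-Tracking in Simulated Colonoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting moments of navigation loss (MNL)
    during simulated colonoscopy from 60 Hz eye-tracking streams. Implements
    I-VT velocity-threshold fixation/saccade detection, per-phase gaze and
    pupillometric feature extraction (saccadic amplitude, inter-fixation
    distance, min-max adjusted pupil size), group statistics with
    significance-driven feature selection, per-class adversarial (DCGAN-style)
    augmentation of tabular feature vectors with a t-SNE overlap check, and an
    LSTM-based MNL/non-MNL classifier evaluated under multiple data-feeding
    strategies. Ships a calibrated synthetic gaze-stream generator so the whole
    pipeline is testable without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
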