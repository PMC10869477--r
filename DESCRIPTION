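Package: seizadapt
Title: Cross-Subject Epileptic Seizure Prediction from Scalp EEG with
    Adversarial Domain Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts epileptic seizures from multichannel scalp EEG by
    classifying 10-second windows as pre-ictal or inter-ictal. Provides the
    full pipeline: EDF input/output, notch and band-pass filtering, interval
    labelling around annotated seizures, windowing, normalization and class
    balancing; a compact three-block convolutional classifier (temporal
    filters, depthwise spatial filters, feature filters) with an exposed
    feature embedding; and three feature-based adversarial domain-adaptation
    training regimes (DANN, CDAN, CDAN+E) built on a gradient reversal layer,
    for generalizing to unseen patients under leave-one-patient-out
    evaluation. A synthetic multi-subject cohort generator with controllable
    between-subject spectral shift makes every stage testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
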