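Package: miwl
Title: Mutual-Information Fusion of EEG and Vehicular Signals for Driver
    Mental Workload Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating driver mental workload from the fusion of
    electroencephalographic (EEG) and vehicular telemetry signals. Implements
    an EEG spectral pipeline (Butterworth band-pass filtering, regression-based
    blink correction, overlapping 2 s epoching, three-criteria artifact
    rejection, Hann-windowed power spectral density, individual-alpha-frequency
    anchored band features), a stepwise linear discriminant workload index with
    automatic stopping, histogram and k-nearest-neighbour mutual-information
    estimators, a mutual-information template that weights vehicular features
    by their shared information with EEG band power, and an evaluation harness
    (cross-validation schemes, regression and classification metrics, ROC/AUC,
    exact Wilcoxon signed-rank and DeLong AUC tests). A seeded simulator
    generates coupled EEG/vehicular driving sessions with known latent
    workload for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    ranger,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
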