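Package: intoxgait
Title: Detecting Alcohol-Impaired Gait from Triaxial Accelerometer Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete pipeline for detecting alcohol intoxication from
    waist-mounted smartphone accelerometer recordings of gait. Provides a
    seedable synthetic triaxial gait simulator with class-dependent sway,
    cadence and phase perturbations; a subject-wise preprocessing chain
    (stratified subject-disjoint splitting, per-subject z-scoring, Isolation
    Forest outlier removal, zero-phase Butterworth low-pass filtering,
    overlapping sliding-window segmentation and minority-class random
    oversampling); a handcrafted gait feature bank with mutual-information
    feature selection for classical baselines; a multichannel
    Conv1D-BiLSTM-attention classifier with five selectable attention variants
    and component-ablation builders, trained with Adam, early stopping and
    learning-rate scheduling; subject-level cross-validation; and
    interpretability tools (attention-weight profiles, gait-phase quartile
    analysis, channel-masking ablation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
NeedsCompilation: yes
Config/testthat/edition: 3
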