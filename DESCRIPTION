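Package: histowolf
Title: Grey-Wolf-Optimized Fuzzy-Scoring Residual Networks for Histology Texture Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a hybrid pipeline for benign versus
    malignant histopathology image classification: correlation-based
    redundancy filtering, multilevel fast discrete wavelet texture features,
    an adaptive multi-leader Grey Wolf Optimizer with a Pareto archive and
    hypercube-grid leader election for feature selection and hyperparameter
    tuning, and a compact residual convolutional network whose output stage is
    a fuzzy scoring layer with a modified backpropagation error. Includes a
    synthetic histology-texture generator so every stage is testable without
    external data, plus evaluation metrics, significance tests, and a
    four-arm ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage,
    generics,
    rlang,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
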