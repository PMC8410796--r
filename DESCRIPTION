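Package: melbalance
Title: Class-Imbalance-Aware Training and Evaluation for Binary Lesion
    Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training binary medical-image classifiers on
    class-imbalanced data. Implements a class-wise squared-error loss that
    penalises both the total and the gap between the per-class errors, a
    fixed-class-ratio mini-batch sampler, real-time affine image
    augmentation, a reformed fully connected classifier head trained with
    Adam under a triangular2 cyclical learning rate, and an evaluation
    suite for sensitivity/specificity threshold analysis, ROC/AUC, and
    model-versus-reader comparison. Ships a seeded generator of synthetic
    dermoscopy-like lesion images so the whole pipeline is testable
    offline.
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
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
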