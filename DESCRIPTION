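Package: mcnnrf
Title: Multimodal CNN Feature Fusion with Joint Attention and Stacked
    Random Forests for Binary Neurodiagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a three-stage multimodal classification pipeline for
    tabular EEG- and structural-MRI-derived feature vectors: modality-specific
    convolutional branches with per-channel matrix-product feature fusion and
    multi-pooling blocks, a sigmoid cross-modal joint attention mechanism that
    routes each modality's value stack by the other modality's spatial
    attention map, and a stacked random-forest cascade with out-of-fold
    probability augmentation. Includes weighted nearest-neighbour imputation,
    min-max normalization, minimum-redundancy maximum-relevance (MRMR) feature
    selection with grid-based subset sizing and permutation-importance
    verification, a seeded synthetic multimodal cohort generator with planted
    complementary class signal, a full evaluation suite (sensitivity,
    specificity, precision, accuracy, Matthews correlation, ROC/AUC, stratified
    cross-validation), and an ablation harness over fusion strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
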