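Package: synstarr
Title: Synthetic STARR-Seq Analysis of Designed Binding-Site Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies per-variant enhancer activity from synthetic
    STARR-seq screens of designed oligo libraries with degenerate positions.
    Provides exact-match variant counting from paired-end reads,
    negative-binomial differential activity testing (median-of-ratios
    normalisation, locally smoothed dispersion shrinkage, Wald tests,
    Benjamini-Hochberg adjustment) with enhancing/blunting/neutral
    classification, weighted activity logos and consensus motifs, PWM
    log-odds motif weights, pentamer-table DNA shape prediction with
    profile clustering, sequence- and shape-based activity classifiers
    with cross-validated ROC, and expression mean and noise (CV squared)
    from two-channel single-cell fluorescence tables. A synthetic-data
    module simulates screens, reads and bursting-promoter fluorescence
    populations so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
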