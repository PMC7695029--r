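Package: fameclass
Title: Chemometric Discrimination of Wild and Farmed Salmon from GC-FID
    Fatty Acid Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for food-authenticity chemometrics on fatty acid methyl
    ester (FAME) profiles measured by gas chromatography with flame
    ionization detection.  Provides a SummarizedExperiment-based container
    for replicate chromatogram profiles with sample-block structure, a
    calibrated synthetic-data generator emulating the published group
    statistics of wild and farmed Atlantic salmon, information-gain-ratio
    feature ranking with Fayyad-Irani MDL discretization, a binary-search
    minimal-feature selector, PCA and t-SNE embeddings (including a
    transductive t-SNE feature-mapping stage), a seven-classifier bench
    with block-aware holdout and leave-one-sample-out cross-validation,
    and compositional summary statistics with ANOVA/Tukey compact letter
    displays.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, e1071, rpart, randomForest,
    Rtsne, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
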