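Package: cellhypoxia
Title: Cell-Specific Tumor Hypoxia Scoring, Signature Derivation and
    Downstream Genomic, Immunotherapy and Survival Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying tumor hypoxia from bulk and
    single-cell transcriptomes and carrying the score through the
    downstream analyses it supports. Provides a from-scratch single-sample
    gene-set scoring engine (kernel-CDF rank statistic with a weighted
    Kolmogorov-Smirnov-like walk, in the GSVA/ssGSEA family), a four-step
    framework that derives a malignant-cell-specific hypoxia signature
    across multiple single-cell datasets, a focal/arm/chromosome somatic
    copy-number instability score from segmented log2 ratios, association
    and stratification statistics (including hypoxia-by-mutation-burden
    quadrants), a cross-validated model-selection harness for predicting
    immunotherapy response, consensus feature selection with stepwise Cox
    risk and nomogram scores for survival, CRISPR-screen target
    prioritization, and seeded synthetic-data generators with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    methods,
    Rcpp,
    class,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    ranger,
    rpart,
    stats,
    survival,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
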