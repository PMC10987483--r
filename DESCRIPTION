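Package: tmesuite
Title: Tumor-Microenvironment Subtype Discovery and Prognostic Signature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signature-level subtyping of bulk tumor transcriptomes by consensus
    non-negative matrix factorization with cophenetic/dispersion rank selection,
    nearest-centroid projection of subtypes onto external cohorts, Kaplan-Meier,
    log-rank and univariate Cox survival statistics, a three-algorithm
    (LASSO-Cox, random forest, SVM-RFE) prognostic-signature selection ensemble,
    a single-cell QC/normalization/clustering/marker stage with marker-set
    annotation, and permutation-based ligand-receptor interaction testing.
    Includes synthetic bulk and single-cell cohort generators with planted
    ground truth so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    glmnet,
    randomForest,
    e1071,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
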