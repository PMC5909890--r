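Package: mzpanel
Title: Untargeted LC-MS Metabolite Annotation and Biomarker Panel Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for plasma metabolomics biomarker development
    from untargeted LC-MS feature tables: annotation of m/z features by
    monoisotopic-mass matching against a compound library ([M-H]-/[M+H]+
    adducts), generalized-log and auto-scaling normalization with per-feature
    batch adjustment, multi-method biomarker panel selection (LASSO selection
    frequency, linear SVM recursive feature elimination, PLS-DA VIP, random
    forest importance, univariate rankings), logistic-regression ROC
    evaluation with stratified 10-fold cross-validation and external
    replication, and Hanley-McNeil comparison of independent ROC AUCs. A
    seed-deterministic synthetic two-cohort generator emulates case/control
    feature tables with spiked marker compounds, batch effects and
    cohort-specific feature dropout so the whole workflow is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    randomForest,
    mixOmics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
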