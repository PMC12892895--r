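Package: tepclassify
Title: Tumor-Educated Platelet RNA Classification Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates blood-platelet RNA-seq classifiers for
    case/control cancer diagnosis from a transcript count matrix and clinical
    metadata. Provides a synthetic matched-cohort generator with known ground
    truth, quality-control filtering with matched-pair integrity enforcement,
    TMM normalization, factor-based removal of unwanted variation for sex and
    library size, propensity-score matching with caliper-constrained
    nearest-neighbor pairing and balance diagnostics, a particle-swarm
    optimized support vector machine classifier with ANOVA/FDR panel
    selection, an iterated LASSO logistic-regression ensemble with stability
    selection against a binomial random-selection null, and ROC/AUC reporting
    with DeLong confidence intervals and subgroup accuracy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    edgeR,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse,
    withr
Config/testthat/edition: 3
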