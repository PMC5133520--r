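Package: rvpredict
Title: Benchmarking Classifiers for Disease Prediction from Rare-Variant
    Burden and Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation-driven comparison of logistic regression and
    linear/radial support-vector machines for predicting a collapsed binary
    hypertension phenotype from covariates, per-gene rare-variant burden
    (CMC collapsing), and gene expression. Provides a seeded pedigree-based
    cohort simulator with many independent phenotype replicates over fixed
    genotypes, phenotype-replicate collapsing into specific and sensitive
    case definitions, joint expression-by-burden logistic gene selection via
    likelihood-ratio tests, probabilistic classification scored by AUC over
    a factorial evaluation grid (gene lists by expression noise by
    classification replicate by collapse depth), and an ordinary
    least-squares meta-regression of AUC on the grid factors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
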