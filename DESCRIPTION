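Package: switchgs
Title: Genomic Selection for Clonally Replicated Switchgrass Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome prediction for clonally replicated perennial-grass
    association panels. Converts plot-level trial records into analysis-ready
    genotype values (growing-degree-day phenology, studentized-deleted-residual
    outlier screening, REML variance components and BLUPs, clone-mean
    repeatability with delta-method standard errors, Box-Cox transformation),
    prepares SNP dosage matrices (imputation, minor-allele-frequency filtering,
    principal components for population-structure correction), fits RR-BLUP,
    LASSO and elastic-net prediction models, and evaluates them by
    population-grouped ten-fold cross-validation with repeatability-standardized
    prediction accuracies. A simulator for structured multi-population clonal
    trials with known genetic architecture makes every stage testable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    Rcpp,
    data.table,
    jsonlite,
    lme4,
    pracma,
    stats,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
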