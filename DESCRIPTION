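Package: rarepred
Title: Rare-Variant Collapsing and SVM-Based Disease Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses whether collapsed rare variants add predictive value over
    common variants and environmental covariates in case-control disease risk
    prediction. Implements a two-stage variant screen (Fisher's exact
    allele-count test for common SNPs; gene-level presence/absence collapsing
    with covariate-adjusted logistic regression and AIC-based choice between
    the all-rare and nonsynonymous-rare sets per gene), soft-margin linear
    support vector machine risk models, ROC/AUC evaluation, and paired
    replicate-level comparison of models with and without rare variants under
    two experimental designs. Includes a mini-exome style cohort simulator
    (fixed genotypes, gene-grouped SNPs spanning rare and common allele
    frequencies, covariates, and many re-simulated binary trait replicates) so
    the whole pipeline is testable without restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
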