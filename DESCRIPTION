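Package: refeedomics
Title: Medication-Deconfounded Multi-Omics Analysis of Fasting and Dietary
    Intervention Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for longitudinal multi-omics intervention
    studies in which antihypertensive medication changes confound the signal
    of interest. Implements medication-deconfounded univariate screening of
    microbiome, functional-module, immune and clinical features (nested
    linear-model likelihood-ratio tests with Mann-Whitney post-hoc contrasts
    and Cliff's delta effect sizes), donor-stratified PERMANOVA and principal
    coordinates analysis, repeated-measures Spearman correlation networks
    with mixed-model same-donor post-hoc tests and phenotype-immune-microbiome
    triplet assembly, responder stratification from ambulatory blood-pressure
    change, and leakage-safe leave-one-subject-out forward-stepwise
    ridge-logistic response prediction. A fully synthetic cohort generator
    with planted ground truth exercises every stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    lme4,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
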