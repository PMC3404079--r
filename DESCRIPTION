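Package: survSigCV
Title: Cross-Validated Immunogenetic Prognostic Signatures for Censored
    Survival
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates multi-marker genetic prognostic signatures
    from censored survival cohorts. Raw immunogenetic calls (multi-allelic
    HLA loci, biallelic SNP diplotypes, microsatellite fragment lengths) are
    coded into binary carrier and homozygosity indicators, filtered by
    carrier frequency, screened by univariate Cox regression, and combined
    into a multivariate Cox signature by backward elimination. The signature
    is evaluated with leave-one-out cross-validated prognostic-index risk
    groups (Kaplan-Meier curves and log-rank statistic), permutation tests
    for the cross-validated statistic and for added value beyond a clinical
    covariate, cross-endpoint validation of an overall-survival model on
    relapse-free survival, and time-dependent ROC curves for censored data.
    A synthetic-cohort generator with planted hazard effects makes every
    stage testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), survival, jsonlite, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'coding.R'
    'survival-core.R'
    'model-building.R'
    'cv-risk.R'
    'permutation.R'
    'tdroc.R'
    'synthetic.R'
    'pipeline.R'
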