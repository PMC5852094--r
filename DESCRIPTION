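Package: heightMR
Title: Mendelian Randomization of Adult Height on Head and Neck Cancer Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a Mendelian randomization (MR)
    analysis of adult height on head and neck cancer (HNC) risk. Provides a
    seeded case-control cohort simulator with an additive-liability disease
    model, genotype quality control (call rate, Hardy-Weinberg exact test in
    controls, LD pruning, imputation-quality filtering, principal components
    for population stratification), weighted genetic risk score (GRS)
    instrumental-variable analysis, summary-statistics inverse-variance
    weighted (IVW) and MR-Egger estimators, a GRS confounder screen,
    binary-outcome MR power calculations, and paper-shaped descriptive and
    estimate tables, orchestrated by a reproducible pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
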