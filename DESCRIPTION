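Package: firthde
Title: Firth Logistic and Negative Binomial Regression for Case-Control RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression testing for case-control RNA-Seq studies,
    comparing negative binomial regression of counts on disease status against
    classical, Bayes (Cauchy-prior), and Firth penalized logistic regression of
    status on expression. Includes median-of-ratios normalization, a single-gene
    simulation engine with disease-associated binary covariates, empirical
    Type-I-error and power evaluation, stratified permutation machinery, exact
    permutation p-values, a data-adaptive recalibration of test statistics,
    genomic inflation factors, and Benjamini-Hochberg FDR control.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
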