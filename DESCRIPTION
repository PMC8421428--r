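Package: mondrianprs
Title: Mondrian Cross-Conformal Calibration of Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns polygenic risk scores (PRS) into individual-level disease
    predictions with per-class confidence bounds using Mondrian cross-conformal
    prediction (MCCP). Includes a liability-threshold simulator of case-control
    cohorts over a grid of genetic architectures (polygenicity, heritability,
    prevalence), a discovery GWAS with pruning-and-thresholding PRS
    construction, class-conditional (Mondrian) conformal p-values with
    cross-conformal fold averaging, prediction regions with confidence and
    credibility, and evaluation machinery: reliability (calibration) curves,
    coverage, and AUC/PPV/NPV restricted to the predicted subset, with an
    empirical top-x%/bottom-x% comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
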