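Package: lrcv
Title: Validation of Genetic Evaluations by Linear Regression on Partial and
    Whole Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates population accuracy, bias and dispersion of estimated
    breeding values (EBV) by comparing genetic evaluations computed from
    "partial" (truncated) and "whole" (complete) phenotype data, the so-called
    LR method. Provides pedigree and genomic (VanRaden method 1) relationship
    matrices, an animal-model BLUP solver with exact prediction-error
    (co)variances, EM-REML variance-component estimation, the LR statistics
    with their mixed-model theoretical expectations, a stochastic simulator of
    pedigreed populations with optional truncation selection, and replicated
    cross-validation with random masking of records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
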