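Package: cacgrs
Title: Genetic Risk Score by Statin Interaction Analysis of Coronary Artery
    Calcification Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacogenetic cohort analyses of rapid coronary
    artery calcification (CAC) progression. Implements genotype input and
    quality control (minor allele frequency, missingness, Hardy-Weinberg
    exact test, hard-call thresholding), weighted polygenic risk scoring
    with expected-value imputation of missing genotypes, an age- and
    sex-specific CAC percentile progression model with slow/expected/rapid
    classification and extreme-change flagging, and log-linear (modified
    Poisson) relative-risk regression with robust sandwich variance for
    gene-by-drug interaction testing with Bonferroni control. A synthetic
    cohort generator with known ground-truth effects makes the full
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
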