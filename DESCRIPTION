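Package: cfmax
Title: Max-Logistic Competing Risk Factor Classifiers for Cross-Cohort
    Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating max-logistic competing risk
    factor classifiers on tumor/normal gene-expression cohorts. A sample's
    log-odds of disease is the maximum of several linear predictors
    ("competing factors"), each built on a small gene group. The package
    implements the scoring model and its 0-1-loss objective with a
    sparsity penalty on the gene union and factor count, a
    mean/SD/Sharpe-ratio relative-change screening procedure (MVS-CGS),
    a seeded Monte-Carlo subset search with coefficient fitting across
    heterogeneous cohorts, confusion-matrix and stratified evaluation
    with classifier-defined patient subgroups, packaged published
    four-gene colorectal-cancer classifiers with worked-example
    verification, and a planted-truth multi-cohort synthetic data
    generator for end-to-end testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
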