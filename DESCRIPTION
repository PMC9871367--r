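Package: prsboost
Title: Batch-Screened Component-Wise Boosting for Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits sparse polygenic risk scores on large genotype dosage
    matrices by component-wise gradient boosting with correlation-driven
    batch screening: each outer step extracts the variants most correlated
    with the current negative gradient into a batch, inner boosting
    iterations run on that batch until the stored out-of-batch correlation
    overtakes the in-batch ones, and the outer loop stops when validation
    loss no longer improves. Supports squared-error loss for continuous
    traits and log loss for binary traits, mandatory covariates, PLINK 1
    binary genotype input/output, summary-statistics-style score export,
    a genotype/phenotype simulator with configurable heritability,
    sparsity and linkage-disequilibrium blocks, and the usual prediction
    and variant-selection metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
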