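Package: funcann
Title: Continuous Functional Annotations and Heritability Partitioning for GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating continuous per-SNP functional annotations
    against GWAS summary statistics. Implements annotation construction
    (tissue aggregation, quantile matching, allelic-effect scores, region
    restriction, local sequence content, gene-score windows), stratified LD
    score computation from a reference genotype panel, stratified LD score
    regression with block-jackknife standard errors, heritability enrichment
    and standardized effect sizes (tau-star), conditional marginal and
    forward-stepwise analyses meta-analyzed across traits, a weighted k-mer
    enrichment statistic with a permutation null, MAF-matched control
    selection with AUROC evaluation, and a synthetic-data generator that
    reproduces the statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    metafor,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xgboost
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
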