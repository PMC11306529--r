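Package: methrx
Title: Integrated DNA Methylation and Expression Analysis of Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating longitudinal DNA methylation and gene
    expression profiles from treated tumor cohorts. Implements discovery of
    sparse predictive methylation signatures by leave-one-out penalized
    logistic regression with nested cross-validation and majority-vote
    aggregation, translation of CpG signatures into gene expression
    signatures via strongest methylation-expression correlation, hybrid
    score fusion, paired differential methylation testing with
    interquartile-range prefiltering, delta expression-methylation
    quantitative trait locus (emQTL) scanning with spectral co-clustering
    of CpG-gene correlation structure, tumor-purity correction of beta
    values by per-CpG regression, and hypergeometric enrichment of CpGs and
    CpG-gene pairs against chromatin states, transcription factor binding
    sites, gene sets and chromatin loops. A seeded synthetic-cohort
    generator with planted signal supports end-to-end testing without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    glmnet,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
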