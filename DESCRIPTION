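Package: miswire
Title: Enhancer Miswiring Analytics for Fusion-Driven Sarcoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for inferring enhancer miswiring caused by oncogenic
    chromosomal translocations, modeled on the regulatory genomics of
    fusion-positive rhabdomyosarcoma. Implements breakpoint-aware fusion
    transcript construction from gene models, an exonic-imbalance Z
    statistic for allele-specific epistate inference from exon-level
    RNA-seq, ROSE-style enhancer stitching and super-enhancer calling
    with cross-sample rank percentiles and spike-in (RRPM)
    normalization, CTCF convergent-orientation neo-TAD reconstruction
    with insulated-neighborhood classification, and pooled CRISPR
    tiling-screen dropout aggregation by regulatory-element class. A
    synthetic-cohort generator emulates the statistical structure of all
    required inputs so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
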