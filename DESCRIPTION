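Package: promcapr
Title: Downstream Analysis of Promoter Capture-C Interaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidyverse-native toolkit for the downstream analysis of promoter
    Capture-C / Capture Hi-C experiments: in-silico DpnII restriction-fragment
    maps and captured-fragment selection, normalization and pooling of
    upstream-caller interaction tables, significant-interaction filtering and
    peak merging on restriction-fragment distance, regulatory-element
    annotation against TSS/CDK8/ATAC interval sets, gene classification from
    differential-expression and promoter ChIP quantitation, expression-matched
    resampling nulls with empirical p-values, replicate-consistency calling of
    gained and lost interactions, and a seeded synthetic-data generator that
    emulates the upstream interaction caller's output for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    methods,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
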