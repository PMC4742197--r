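Package: racescreen
Title: Exon-Level Break-Score Screening and RACE-Seq Analysis of Fusion
    Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering novel RNA variants in cancer cohorts from
    exon-level expression arrays and targeted 5' RACE sequencing (RACE-seq).
    Implements the expression break score (EBS), a per-gene, per-sample
    change-point statistic that flags sample-specific overexpression of a
    gene's 3' end, together with candidate nomination filters; in-silico
    planning and validation of nested RACE assays; RACE-seq read analysis
    including adapter trimming, primer-anchored chimeric-read retrieval,
    exact split mapping, fusion-scaffold split/spanning read counting and
    junction k-mer searches; splice-junction filtering and cross-cohort
    validation; and seeded synthetic-data generators that provide ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
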