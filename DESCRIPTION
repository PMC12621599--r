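Package: tailscape
Title: Poly(A) Tail and mRNA 3'-End Dynamics from Long-Read Per-Read Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of mRNA 3'-end dynamics from nanopore-style per-read
    poly(A) tail tables: per-transcript differential adenylation (rank-sum
    tests with Benjamini-Hochberg adjustment, Cohen's d effect sizes),
    simplified negative-binomial Wald differential expression,
    polyadenylation-site calling from read 3' ends with Fisher-exact
    differential usage and upstream hexamer profiling, FIMO-style PWM
    scanning of 3'UTRs for cytoplasmic polyadenylation elements with exact
    p-values, discovery of semi-templated poly(A) tails arising from A/T-rich
    3'UTR termini, and discrimination of transcriptional induction from
    cytoplasmic polyadenylation. Includes a seeded synthetic-data generator
    that plants each mechanism so every stage is testable against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
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
    utils
Suggests:
    DESeq2,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
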