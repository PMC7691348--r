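Package: umilink
Title: UMI-Linked Consensus Calling for Long-Read Sequencing of Gene Variant Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for unique-molecular-identifier (UMI) linked consensus sequencing of
    amplicon libraries on error-prone long-read platforms. Simulates error-prone-PCR
    variant libraries, UMI-tagged constructs and nanopore-like reads with ground truth;
    extracts UMIs by probe alignment and groups reads with a fast greedy agglomerative
    clustering; derives per-cluster consensus variant calls from a base-space pileup with
    read-support and mutation-count filters; and analyses directed-evolution rounds via
    demultiplexing, variant deduplication, sequence-similarity networks, founder-variant
    detection, positional enrichment and sign/magnitude epistasis classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
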