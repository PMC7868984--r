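Package: polysv
Title: Long-Read Structural Variant Post-Processing for Polyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of long-read structural variant (SV) calls in
    polyploid crop genomes. Provides stringent quality filtering of
    Sniffles-dialect call sets, breakpoint-proximity merging of SV across
    samples with geometric force-calling and cross-platform concordance,
    gene-model and genomic-window annotation with subgenome bias statistics,
    read-depth copy-number detection from block medians, QTL-interval
    candidate prioritization, presence/absence matrix export to PHYLIP with
    neighbor-joining trees, and a seeded truth-tracked synthetic data
    generator so every stage is testable without large sequencing datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    ape,
    phangorn,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
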