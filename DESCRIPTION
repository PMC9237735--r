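Package: splicestack
Title: Cell-Type-Stratified Read Stacks for Single-Cell Long-Read Isoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns per-read exon structures from single-cell long-read RNA
    sequencing into cell-type-stratified, intron-chain-clustered read stacks
    drawn on an exon-preserving compressed coordinate axis. Alternative
    (cassette) exons are flagged by a percent-spliced-in window computed over
    all overlapping reads, reference mismatches (SNVs, insertions, deletions)
    are located from alignments and frequency-filtered, and every read can be
    exported as a BED12 track for the UCSC Genome Browser. A seeded synthetic
    fixture generator produces ground-truthed toy genes, reads, alignments and
    reference sequence so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    generics,
    ggplot2,
    methods,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    xml2
Config/testthat/edition: 3
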