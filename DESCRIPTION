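Package: insertmap
Title: Mapping Genomically Integrated DNA Payloads from Long Junction-Capture Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating genomic integration sites of exogenous DNA
    payloads (viral vectors, transposons, knock-in donors) from long
    junction-capture sequencing reads. Implements UMI-based deduplication and
    consensus building, anchored insertion-site peak calling with a
    beta-density coverage-shape filter, family-level putative peak calling
    for insertions landing in repetitive elements, annotation of calls with
    repeat and genomic-feature context, ROC-AUC association of insertion
    sites with interval feature tracks, and seedable simulators (synthetic
    genomes with planted repeat families and insertions, structured junction
    reads, read-length and limit-of-detection studies) so the whole workflow
    is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
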