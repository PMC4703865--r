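Package: pausekit
Title: RNA Polymerase II Promoter-Proximal Pausing Analysis from ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based quantification of ChIP-seq occupancy around
    transcription start sites for studies of RNA polymerase II
    promoter-proximal pausing and pause release. Derives strand-aware
    TSS-proximal, gene-body and flanking windows from a GTF annotation,
    assigns aligned reads to windows under a single-gene rule, scales
    libraries to a common effective depth, computes pausing indices and
    condition contrasts, calls enriched regions against a matched input
    with a Poisson model, and performs cohort-level bootstrap
    difference-of-medians inference with empirical confidence intervals.
    Includes a synthetic ChIP-seq read simulator with closed-form expected
    pausing indices for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
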