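Package: ncceScan
Title: Genome-Wide Screen for Conserved NKX-COUP-TFII Composite Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements a screen for composite cis-regulatory elements
    formed by an NKX homeodomain motif and a COUP-TFII nuclear-receptor
    half-site under a center-to-center spacing constraint. Scans conserved
    genomic regions for IUPAC consensus motifs on both strands, pairs
    NKX-role and partner-role hits within conserved elements under spacing
    windows, verifies cross-species synteny of both motifs through UCSC
    chain alignments with a built-in interval mapper, assigns elements to
    nearest-TSS genes, builds wide-spacing and scrambled-motif control
    classes, and tests gene-set term enrichment of composite-element genes
    against each control with exact one-sided tests and BH correction. A
    seeded synthetic two-genome generator with a truth manifest makes every
    stage verifiable at desk scale.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.3),
    GenomicRanges,
    Biostrings
Imports:
    methods,
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
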