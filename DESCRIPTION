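Package: sRNAbud
Title: Small RNA Sequencing Analysis of Plant Flower-Bud Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative small RNA sequencing of two
    plant libraries: adapter trimming and read cleaning with a per-category
    ledger, collapsing to unique tags, classification against ncRNA and
    mature miRNA references, hairpin-based discovery of novel miRNAs with
    miRNA* duplex evidence under an in-package minimum-free-energy folding
    engine, per-million normalization with the Audic-Claverie exact count
    test for differential expression, and Allen-rule miRNA target scanning.
    Includes a synthetic library generator with full ground truth so every
    stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rcpp,
    stringi,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
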