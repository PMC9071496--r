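Package: rbptm
Title: Posttranslational Modification Landscape Analysis for RNA-Binding Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Harmonizes posttranslational modification (PTM) site catalogs
    onto a canonical proteome and analyzes the PTM landscape of RNA-binding
    proteins (RBPs): per-type distribution statistics and enrichment tests,
    conservation contrasts against resampled per-protein backgrounds,
    enzyme-substrate pairing over protein-protein interaction networks
    (ME/M/E classification), cancer-mutation proximity to PTM sites,
    standardized UV-crosslink interface windows with distance-decay
    statistics, strand-aware eCLIP peak-gene intersection, and flat-file
    atlas export. Ships a seeded synthetic-data generator that plants each
    of the effects the analyses are designed to detect, so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
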