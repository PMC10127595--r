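Package: lysoscan
Title: Delineation of Spontaneously Induced Prophages from Phage-Fraction
    Read Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for locating active prophages in lysogenic bacterial
    genomes by sequencing the spontaneously produced phage fraction of a
    culture and mapping the reads back to the host genome. Provides a
    synthetic lysogen simulator (planted prophages, transduction-style
    flanking enrichment, multi-copy insertion sequences, contaminant
    reads, culture count series), a seeded k-mer read mapper with
    configurable multi-mapping policy, per-base coverage tracks with
    BedGraph input/output, fold-enrichment segmentation that calls and
    classifies prophage cores, over-packaged flanks and repeat-driven
    artifact peaks, interval comparison against external prophage
    predictions, insertion-sequence mobilome profiling, and culture
    growth and virion morphometric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    tibble,
    utils
Suggests:
    BiocGenerics,
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
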