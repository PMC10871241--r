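Package: bigbits
Title: Read, Write and Query BigWig and BigBed (BBI) Files
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pure-R implementation of the Big Binary Indexed (BBI) file
    formats, BigWig and BigBed, covering the complete life cycle of these
    files: parsing and emitting their text precursors (bedGraph, Wiggle,
    BED, chrom.sizes, autoSql schemas), streaming single-pass creation of
    indexed, block-compressed BigWig and BigBed files with multi-resolution
    zoom summaries, and random-access queries for intervals, per-base
    values, zoom records and region statistics. Includes drop-in
    command-line tools mirroring the classic UCSC utilities
    (bedGraphToBigWig, bedToBigBed, bigWigAverageOverBed, bigWigMerge,
    bigWigInfo, bigBedInfo, bigWigToBedGraph) and a seeded synthetic-data
    generator for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, data.table, parallel
Suggests: testthat (>= 3.0.0), rtracklayer, GenomicRanges, jsonlite
Config/testthat/edition: 3
biocViews: DataImport, Epigenetics, Sequencing, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
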