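Package: trackperm
Title: Typed Genomic Tracks and Null-Model Randomization Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Represents genome annotation tracks as five abstract genomic
    types (unmarked/marked points, unmarked/marked segments, per-base-pair
    functions) and compares pairs of tracks under user-specified null
    models.  A null model combines a preservation rule per track (from
    preserve-everything down to preserve-only-base-pair-counts) with a
    randomization process, optionally driven by a nonnegative per-base
    intensity built from confounder tracks.  P-values are computed exactly,
    asymptotically, or by standard or sequential Monte Carlo, either
    globally or per bin with Benjamini-Hochberg false discovery rate
    correction.  Includes a catalogue of type-pair analyses, BED/WIG/
    chrom.sizes input, a synthetic-track simulator for null-model
    calibration, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'genome.R'
    'track-model.R'
    'track-io.R'
    'binning.R'
    'statistics.R'
    'catalogue.R'
    'null-models.R'
    'intensity.R'
    'mc-inference.R'
    'simulator.R'
    'cli.R'
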