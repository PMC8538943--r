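Package: larvalID
Title: DNA Barcode Identification of Cryptic Insect Larvae and Seasonal
    Phenology Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying morphologically cryptic insect larvae
    (such as turfgrass billbugs, Sphenophorus spp.) from mitochondrial COI
    barcode sequences.  Builds consensus contigs from paired forward and
    reverse Sanger-style reads, aligns barcode sets with a built-in
    progressive aligner, computes p-distances, percent sequence similarity
    and Kimura two-parameter (K2P) distances with pairwise deletion,
    performs barcode-gap analysis, builds neighbour-joining trees with
    nonparametric bootstrap support, and assigns species to unknown larval
    sequences both by average-similarity thresholding and by placement in
    well-supported clades.  Identified larvae are combined with
    head-capsule morphometrics into seasonal phenology and
    species-composition tables.  A seeded sequence and field-season
    simulator generates fully labelled test data so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
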