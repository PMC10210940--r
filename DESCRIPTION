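Package: stcminer
Title: Genome Mining and Clade Classification of Fungal Sesquiterpene Cyclases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers candidate sesquiterpene cyclase (STC) genes in predicted
    fungal proteomes and classifies them into four cyclization clades. The
    pipeline chains a Smith-Waterman similarity screen against characterized
    seed enzymes, a metal-binding motif and length filter cascade, progressive
    multiple alignment with physicochemical-category distance dendrograms for
    clade assignment, discriminative motif discovery and motif-based
    reassignment, profile hidden Markov model construction and glocal search
    with a gathering threshold and a second-generation refinement step, and
    tandem gene duplication analysis from scaffold gene order. A seeded
    synthetic-data generator builds planted clade families, decoy proteins and
    genome layouts so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
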