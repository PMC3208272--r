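Package: mirseeker
Title: Homology-Based Discovery of Conserved Plant miRNA Precursors in EST Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering conserved microRNAs in flower-derived
    EST libraries by gapless homology search against multi-species mature
    miRNA reference sets, folding candidate precursors with a built-in
    minimum-free-energy dynamic program, scoring stem-loops with the standard
    precursor metrics (MFE, AMFE, MFEI, A+U content) and hairpin acceptance
    criteria, analysing the thermodynamic effect of species-specific
    nucleotide substitutions on precursor stability, and comparing expression
    via tag-count tests, microarray detection calls and comparative
    delta-delta-Ct quantification. Includes a seeded synthetic-data generator
    that emulates 454-style flower EST libraries with planted precursors and
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
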