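Package: MetaGeneDSN
Title: Gene Prediction in Metagenomic Fragments with Deep Stacking Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies protein-coding open reading frames (ORFs) in short
    metagenomic DNA fragments. Candidate ORFs (complete and fragment-truncated)
    are enumerated in all six reading frames, encoded as a fused 119-dimensional
    descriptor (ORF length coverage, monocodon usage, monoamino acid usage, and
    Z-curve parameters for codon-position-specific nucleotides and phase-specific
    dinucleotides), and classified as coding or noncoding by a deep stacking
    network whose per-module output weights are solved in closed form by least
    squares, with restricted Boltzmann machine pretraining of the bottom module
    and gradient-based fine tuning of the input weights. Includes a synthetic
    prokaryote-like genome simulator with planted codon-biased genes, balanced
    subsampling, stratified k-fold cross-validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Metagenomics, GenePrediction, Classification, Sequencing
RoxygenNote: 7.3.3
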