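Package: supfmut
Title: Mutation Calling and Spectra for Barcoded supF Shuttle-Vector Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of forward-mutagenesis assays that sequence a randomly
    12-nt-barcoded supF shuttle-vector library by paired-end amplicon NGS.
    Provides a synthetic read simulator with a ground-truth table, index
    demultiplexing, overlap-based read-pair merging, anchored barcode
    extraction with whitelist Hamming-1 error correction, per-barcode variant
    calling with variant-frequency thresholds, six-class variant typing,
    sequencing-error discrimination, mutation-frequency estimation, and
    strand-resolved trinucleotide (192-context) mutation spectra.
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
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
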