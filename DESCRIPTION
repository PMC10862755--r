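Package: cloudfb
Title: Sparse Profile Hidden Markov Model Search with Pruned Cloud
    Forward/Backward
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profile hidden Markov model (pHMM) homology search for protein
    sequences using a sparse approximation of the Forward/Backward algorithm.
    A seeded, pruned anti-diagonal flood fill ("cloud search") locates the
    region of the dynamic-programming matrix holding essentially all of the
    alignment probability mass; Forward/Backward, posterior decoding and
    maximum expected accuracy alignment are then computed over a padded
    flat-array sparse matrix restricted to that region.  Includes readers for
    HMMER3 ASCII profiles and FASTA, k-mer based seeding, null-score
    calibration with P-value/E-value reporting, a staged filter pipeline, and
    a synthetic benchmark generator for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
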