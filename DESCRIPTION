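Package: dnastore
Title: Random-Access DNA Data Storage with Nanopore-Tolerant Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end codec for DNA-based data storage designed around
    error-prone portable (nanopore) sequencers. Arbitrary byte streams are
    encoded into addressed, GC-balanced 1,000-base DNA blocks using a
    constrained 14-bit-to-8-base code, 16-base address sequences with
    guaranteed pairwise Hamming distance, and homopolymer check codes that
    correct bounded-magnitude run-shortening errors. A calibrated
    substitution/insertion/deletion channel simulates MinION-like reads with
    deletions biased into homopolymer runs, and the decoder recovers the
    stored bytes via exact-address demultiplexing, multi-preset progressive
    multiple-sequence-alignment consensus, majority-homopolymer aggregation,
    balance-constrained iterative polishing, and algebraic correction of the
    homopolymer length sequence. Single blocks can be decoded selectively by
    address (in-silico random access).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
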