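Package: coocpair
Title: Discovery of Co-Occurring Motif Pairs in Intronic Flanks of Exons
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements base-bias-corrected co-occurrence (BBC-COOC)
    testing for short motif pairs that co-occur in the intronic regions
    flanking internal exons. Exons are stratified on the GC content of
    their two flanking windows into an equal-occupancy grid, a corrected
    expectation for each ordered motif pair is accumulated across the
    grid, one hypergeometric margin is adjusted to match that
    expectation, and exact tail probabilities are computed for every
    pair of k-mers. The package also provides GC-balanced shuffle
    controls, distance scans of window placement, pseudo-exon and
    pseudo-splice-site construction with position-weight-matrix
    consensus scoring, exon-strength comparisons on GC-matched exon
    sets, pairing-conservation and SNP-density statistics, a
    permutation test for tissue-biased expression of host genes, the
    synergy index for minigene reporter readouts, and a seeded
    synthetic-corpus generator with a planted-motif truth ledger for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Matrix, stats, utils, graphics
Suggests: testthat (>= 3.0.0), Biostrings, rtracklayer, GenomicRanges,
    vcfR, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
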