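Package: earpipe
Title: Small RNA, Degradome and Expression Analysis of Developing Maize Ears
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale reimplementation of the computational pipeline used to
    profile microRNAs during maize ear development: collapsing and
    perfect-match mapping of small-RNA reads with annotation-class
    partitioning, hairpin-precursor excision and minimum-free-energy folding
    with an explicit exclusion ledger and miRNA/miRNA* duplex criteria,
    degradome (PARE) cleavage-site calling with repeat-normalized tag
    abundance and CleaveLand-style target categories 0-4, and stage-wise
    differential expression by one-way ANOVA with Fisher's LSD post-hoc
    tests. A synthetic-data generator plants miRNA precursors, cleavage
    sites and stage effects with a known truth set so every stage of the
    pipeline is testable without external downloads; tables printed in the
    original study are packaged as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
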