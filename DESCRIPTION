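Package: cnvconsensus
Title: Consensus Benchmark Construction for Somatic Copy-Number Variation
    Call Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds high-confidence somatic copy-number variation (CNV)
    benchmark sets from many caller-by-replicate call sets on a
    hyper-diploid cancer genome. Provides exact length-based genomic
    interval algebra (normalization, intersection, Jaccard concordance,
    multi-way disjoint partitioning), copy-number based gain/loss/LOH
    classification, a replicate-group consensus scoring system with four
    confidence levels, validation against orthogonal technologies with
    conflict resolution and breakpoint trimming, region-based precision /
    recall / F1 evaluation, length-weighted ploidy estimation, and a
    synthetic cohort generator that emulates imperfect CNV callers so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
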