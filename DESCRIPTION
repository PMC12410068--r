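Package: SLcallR
Title: Spliced-Leader Detection and Operon Prediction from Long RNA Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects spliced-leader (SL) trans-splicing events in the
    unaligned 5' ends of spliced long-read RNA alignments using a
    Smith-Waterman local alignment augmented with continuity, reference
    3'-proximity and query 5'-proximity terms, normalized to a unit-scale
    SL score. A set of random control sequences provides a background
    score distribution from which a dynamic, fold-change-based cutoff is
    derived to select reads carrying high-confidence SL sequences. SL
    types (SL1 versus SL2-family variants) are assigned per read and
    aggregated per gene to classify upstream/downstream operon roles and
    to predict eukaryotic operon structures, which are written as GFF3
    and can be benchmarked against a reference operon annotation. A
    deterministic simulator generates synthetic genomes, annotations,
    trans-spliced reads, alignments and truth tables so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
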