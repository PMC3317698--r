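Package: miRglean
Title: Small RNA Sequencing miRNA Discovery with Hairpin Folding and
    Target Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis toolkit for plant
    miRNA discovery. Reads are quality filtered, adapter trimmed and
    collapsed to unique tags; tags are classified against bundled ncRNA
    and mature miRNA catalogs; unannotated tags are mapped to a genome,
    candidate precursors are excised and folded with a deterministic
    minimum free energy engine, and hairpins are evaluated against plant
    miRNA annotation criteria including the Dicer two nucleotide 3'
    overhang and miRNA* read support. Targets are scored with a
    seed-weighted complementarity penalty scheme and qRT-PCR delta-CT
    summaries are computed. A synthetic genome and read simulator with a
    truth ledger supports precision/recall benchmarking of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
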