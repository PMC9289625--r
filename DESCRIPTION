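Package: ltrdomains
Title: Discovery of Non-Canonical Protein Domains in Plant LTR Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An offline, desk-scale pipeline for discovering protein domains
    that have become fixed in plant LTR retrotransposons. Loci are anchored on
    reverse transcriptase (RT) matches found by sliding position-specific
    scoring matrices over six-frame translations, extended, clustered and
    collapsed into family consensus sequences, then annotated for canonical and
    non-canonical domains with a per-species fixation ("n5") filter. Companion
    modules characterize full-length elements (LTR pairs, TIRs, PBS, PPT, ORFs,
    dual RNase H, dot plots, divergence-limited masking), place RT and
    dioxygenase domains on bootstrapped neighbor-joining trees, and quantify
    the biochemical validation assays (Hill-transformation dissociation
    constants from EMSA series, m6A/A ratios and demethylation percentages from
    chromatograms). A synthetic-genome generator with ground-truth annotations
    makes every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    ape,
    pracma,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
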