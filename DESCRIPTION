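Package: alignoise
Title: Sliding-Window Monte Carlo Detection of Random Similarity in
    Multiple Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies, for every pair of sequences in a multiple sequence
    alignment, the balance of non-random versus random similarity using a
    sliding-window Monte Carlo resampling test. Per-pair sign profiles are
    summarized into a pairwise similarity matrix (excluding globally
    invariant sites), and the matrix can be projected onto a phylogenetic
    tree to score terminal and internal branches, flagging splits whose
    mean cross-split similarity is negative as potentially unreliable
    despite high node support. Includes a sequence-evolution simulator
    (gamma rate heterogeneity, invariant sites, optional indels) for
    generating test alignments along trees, and SVG rendering of the
    similarity heatmap and tagged tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    parallel,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
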