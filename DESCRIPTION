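Package: knotarch
Title: Domain-Architecture Evolution of Knottin (ICK) Toxin Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects inhibitor cystine knot (ICK) cysteine frameworks and
    domain valency in spider-toxin precursors, reconstructs the molecular
    mechanism behind tandem-domain gains and losses (nonsense point mutation,
    frameshifting deletion, unequal crossing-over, transposable-element
    disruption), searches 3'UTRs for pseudogenized domain remnants, quantifies
    transposable-element association around toxin genes by permutation, and
    counts valency transitions on phylogenies under Dollo and unconstrained
    parsimony. Ships a truth-tagged synthetic toxin-family simulator so every
    stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    BiocGenerics,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
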