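Package: mirnaome
Title: Discovery, Validation and Regulatory-Network Analysis of a Tissue miRNAome
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for microRNA discovery
    and regulation analysis in a mammalian genome: homology-based detection of
    conserved pre-miRNAs, de-novo stem-loop discovery with a built-in
    nearest-neighbor folding engine and a triplet-element hairpin classifier,
    bootstrap-based calling of mature 5'/3' endpoints from tiling-array
    fluorescence, spike-in absolute quantification, read-coverage confidence
    classification, seed-based 3'UTR target prediction with expression
    anti-correlation filtering, and assembly of tissue-specific bipartite
    (permissive/repressive) miRNA-mRNA regulatory networks. A synthetic-data
    module generates every input with planted ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    ape,
    limma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
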