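Package: ddiscape
Title: Structural Landscape of Protein Domain-Domain Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the structural landscape of intra-chain
    domain-domain interfaces in multidomain proteins. Extracts heavy-atom
    contact interfaces between structural domains, performs non-sequential
    interface structural alignment scored by the interface-similarity score
    (IS-score) together with TM-score comparison of whole domains, builds
    domain-level non-redundant datasets and structurally-unrelated template
    libraries, searches each query interface for its closest structural
    match, and analyses the connectivity of interface structural space as a
    directed graph (k-th neighbour fractions, k-closure, strongly connected
    components). Includes a deterministic generator of synthetic multidomain
    structures with planted interface similarity so the whole pipeline can be
    exercised end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
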