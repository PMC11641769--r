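Package: S1Domains
Title: Census, Correspondence and Phylogeny of Tandem S1 Domain Repeats
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and counts RNA-binding S1 (OB-fold) domain repeats in
    protein sequences with a position-specific scoring profile, builds a
    census of domain counts across the three domains of life, computes
    per-domain-position percent-identity matrices between taxon groups,
    calls best domain correspondences, and reconstructs neighbor-joining
    trees from identity-derived distances. Ships a bead-on-a-string
    multidomain sequence simulator that provides ground truth (domain
    coordinates, source-position mapping, generating tree) for every
    stage, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    Rcpp,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, Phylogenetics, Classification
RoxygenNote: 7.3.3
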