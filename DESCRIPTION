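Package: rinpep
Title: Monomer-Pair Fingerprints for Nonribosomal Peptide Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects biosynthetic patterns in nonribosomal peptides by
    reorganizing NRPS gene-cluster monomer predictions and known-compound
    backbones into canonical alphabetized monomer pairs (pairs of
    predictions, POPs, and pairs of existent compounds, PECs). Provides a
    three-predictor consensus caller with an unresolved "nrp" placeholder,
    a 1/0.5/0 match-point system for validating predictions against known
    backbones, binary presence/absence matrices with Jaccard-index
    similarity and Euclidean average-linkage clustering, POP distribution
    tables (global, per compound cohort, per dendrogram branch),
    organism-to-compound homology networks exportable as SIF/GraphML, and
    a seeded synthetic gene-cluster generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    igraph,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
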