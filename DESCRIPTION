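Package: taxascreen
Title: Taxon-Targeted Screening of Amplicon Metabarcoding Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reference-guided pipeline for finding, validating and analysing
    sequences of a single target family (by default the diatom family
    Leptocylindraceae) in large SSU rDNA (V4/V9) amplicon datasets. Implements
    global-identity best-hit/LCA and consensus taxonomic assignment,
    reference-seeded capture clustering at 0.90 identity with OTU formation at
    0.97, singleton/doubleton removal, a two-parent chimera screen, phylogenetic
    validation of captured OTUs against a rooted reference tree (template
    threading, neighbor-joining, clade-based species assignment, parsimony
    tree-length skewness), an iterative similarity rule for mining annotated
    sequence collections, per-sample normalisation and biogeographic tables,
    exact conditional (Audic-Claverie) differential tag-count tests, rarefaction
    and OTU-sharing summaries, and a synthetic-data generator so that every
    stage can be exercised offline against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    vegan,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    jsonlite
Config/testthat/edition: 3
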