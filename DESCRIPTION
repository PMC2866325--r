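Package: genegauge
Title: Scoring the Phylogenetic Utility and Signal of Gene Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the value of candidate gene regions for molecular
    phylogenetics along two axes: matrix-intrinsic "utility" statistics
    measured before any tree inference (aligned length, variable and
    parsimony-informative sites, minimum state changes, mean uncorrected
    p-distance), and tree-based "signal" statistics measured after
    inference (ensemble consistency and retention indices, and taxonomic
    congruence scored from binary group-membership characters: proportion
    of monophyletic taxa, taxon consistency index and taxon retention
    index). Includes a Fitch/Hartigan parsimony step counter that handles
    polytomies and missing states, rank-structured aggregation across
    genus, subfamily, family and superfamily, a coherent synthetic-data
    generator (Yule trees, JC69/K2P sequence evolution, clade-based
    taxonomies with controlled perturbation), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
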