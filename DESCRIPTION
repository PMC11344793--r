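Package: assemblnet
Title: Agglomerative Co-Occurrence Networks and Functional Redundancy in
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed agglomerative co-occurrence networks from binary
    genus-by-sample occurrence tables. Occurrence probabilities are modelled
    with environment-specific maximum-entropy margin models; pairwise
    aggregation scores are Poisson-binomial tail probabilities calibrated
    against fixed-margin (curveball) null ensembles with a false-positive-rate
    controlled Z-score cutoff. A conditional clustering algorithm lets the same
    taxon join different partners in different sample subsets; multi-run
    consensus networks carry node and edge support. Downstream tools quantify
    functional and phylogenetic redundancy of assemblages against constrained
    random assemblages, classify pathways as redundant, specific or missing,
    and relate amino-acid auxotrophy to biosynthetic cost. Seeded synthetic
    generators with known ground truth support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
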