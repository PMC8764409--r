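Package: salinet
Title: Community Assembly and Interaction Networks Along Lake Salinity
    Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for analysing bacterial community turnover
    along salinity gradients: rarefaction, alpha diversity, core-community
    occupancy, Levins niche breadth, Bray-Curtis dissimilarity with
    permutational multivariate analysis of variance, a multivariate
    regression tree on environmental predictors, the beta nearest taxon
    index (betaNTI) phylogenetic null model with its selection thresholds,
    an ensemble co-occurrence network built from five association measures
    with permutation and bootstrap edge support, Simes p-value merging and
    Benjamini-Hochberg false discovery rate control, and network topology
    metrics standardised against Erdos-Renyi random-graph nulls.  A
    synthetic salinity-gradient community generator with known niche
    parameters and planted taxon associations makes every stage testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
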