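Package: herdprox
Title: Proximity Interaction Networks for Housed Dairy Herds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and analyses proximity interaction networks for
    permanently housed dairy cattle tracked by an indoor local positioning
    system. Provides a synthetic herd-trajectory generator with known
    ground truth, a trajectory cleaning pipeline (barn-region filtering,
    stuck-sensor removal, moving-average smoothing, stationary-day
    removal), sustained-proximity interaction detection per functional
    barn zone, daily weighted network construction with basic network
    measures, and permutation-based inference: social differentiation
    against a uniform-association null, node-label permutation
    Kruskal-Wallis and Wilcoxon comparisons, Mantel matrix correlations
    for temporal stability and attribute assortment, and Bonferroni
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
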