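Package: antclust
Title: Ant Colony Optimization Clustering for Athlete Performance Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Swarm-intelligence clustering of multivariate athlete
    performance data. Ants construct Hamiltonian paths over the samples,
    biased by pheromone trails and inverse distance; partitions are
    extracted by cutting the longest path edges, and trails evaporate and
    are reinforced in proportion to partition quality. Includes internal
    validation (silhouette coefficient, Davies-Bouldin index), optimal
    cluster-to-label matching with supervised scores, k-means and DBSCAN
    comparators, parameter grid search with repeated seeded runs, a
    synthetic athlete archetype generator with known ground truth, and a
    command-line interface. All entry points take data frames and return
    tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
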