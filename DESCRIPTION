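Package: wardl1
Title: Ward's Hierarchical Clustering Generalised to Manhattan Distances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agglomerative hierarchical clustering with Ward's linkage
    generalised beyond squared Euclidean distances via the between-cluster
    e-distance and its Lance-Williams recurrence, so that Manhattan (and any
    Minkowski-power) point distances can drive a least-absolute-error Ward
    objective. Includes alignment-free n-gram signature extraction for text
    and biological sequences, internal cluster-validation measures
    (silhouette, Dunn index, connectivity), Robinson-Foulds tree comparison
    with Newick input/output, and a seeded synthetic corpus generator that
    evolves first-order Markov character sources along a planted tree for
    end-to-end topology-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    cluster,
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
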