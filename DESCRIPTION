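Package: paretosig
Title: Gene-Signature Discovery via Pareto-Optimal Cluster-Number Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end discovery of discriminative gene signatures from
    two-group expression data. Differentially expressed genes are found with
    an empirical-Bayes moderated t-test and a volcano bi-filter, the number
    of co-expression modules is chosen by Pareto-ranking twelve bootstrap
    cluster-stability objectives (k-means, neural gas and single-linkage
    clustering crossed with four partition-agreement indices), modules are
    extracted by k-means at the selected size, the module with the highest
    average pairwise Spearman correlation becomes the signature, and the
    signature is validated with a nearest-shrunken-centroid classifier under
    repeated stratified cross-validation. Includes a synthetic-data
    generator with planted differential expression and correlated modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
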