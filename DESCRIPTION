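Package: ahcut
Title: Divisive Hierarchical Clustering with the Arithmetic-Harmonic Cut
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Top-down hierarchical clustering of distance and gene-expression
    data by recursive graph bipartition under the arithmetic-harmonic cut
    objective, which jointly maximises the total distance across a split and
    the sum of reciprocal distances within each side. Provides an exact
    backtracking solver for small instances, the greedy construction used by
    the fixed-parameter decision procedure, and a memetic optimiser with a
    ternary-tree pocket/current population, differential greedy crossover and
    variable neighbourhood search. Includes centred-correlation distances for
    expression matrices, planted-partition and multivariate-normal synthetic
    data generators, Newick export of dendrograms, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tibble,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
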