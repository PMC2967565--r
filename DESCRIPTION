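Package: grndisc
Title: Discretization Methods for Gene Regulatory Network Inference from
    Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("Maintainer", "grndisc", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discretizes time-course gene-expression matrices by five
    unsupervised methods (equal-width, equal-frequency, row k-means,
    column k-means, and the bidirectional "bikmeans" product rule),
    infers gene regulatory networks from the discretized data with three
    algorithms (K2 with a time-of-initial-change node ordering, greedy
    hill-climbing DAG search, and an ARACNE-style mutual-information
    filter with data-processing-inequality pruning), and benchmarks
    discretizer x algorithm x interval-count combinations on simulated
    ground-truth networks using sensitivity, specificity and total
    accuracy, with a balanced three-way ANOVA and Tukey-Kramer
    marginal-means comparison. Includes a deterministic synthetic
    time-course simulator that stands in for resampled yeast microarray
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
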