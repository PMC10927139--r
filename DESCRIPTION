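Package: iggpso
Title: Hybrid Feature Selection by Information-Gain Ranking and Grouping
    Binary Particle Swarm Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection for high-dimensional, small-sample expression
    data. Features are scored by information gain on discretized expression
    values, ranked, and partitioned into contiguous groups of approximately
    equal total information gain. A binary particle swarm then searches the
    groups incrementally: within the active group pool the swarm maximizes
    cross-validated classification accuracy, and when the search stagnates the
    next group is appended; candidate group-level subsets are compared by a
    weighted accuracy/subset-size objective. The package also provides the
    standard filter baselines (information gain, chi-square, Pearson
    correlation), a plain binary particle swarm wrapper, filter+wrapper
    hybrids, cross-validated subset evaluation with SVM or KNN backends, a
    synthetic expression-data generator with planted informative, redundant,
    and irrelevant features, and the Friedman omnibus test for comparing
    selection algorithms across datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
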