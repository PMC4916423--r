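Package: fuzzperm
Title: Fuzzy Permutation Method for False Discovery Rate Control
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Randomized ("fuzzy") permutation p-values for multiple testing
    in large-p-small-n two-group studies. A tiny uniform fuzz term added to
    each test p-value breaks the ties that make rank-based and permutation
    p-values discrete at small sample sizes, yielding p-values that are
    uniform(0,1) under the null and hence well-calibrated Storey q-values.
    Includes vectorized two-sample Student t and exact Wilcoxon rank-sum
    tests across many variables, standard (tie-conservative) permutation
    comparators, Storey pi0 estimation and q-value computation, a synthetic
    data generator for four distribution families with known truth, and a
    false-discovery-proportion calibration benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: MultipleComparison, StatisticalMethod, GeneExpression, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
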