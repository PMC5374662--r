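Package: batchbench
Title: Benchmarking Batch-Effect Correction and Batch-Resistant Feature
    Selection in Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates spectral-count proteomics data with known class
    effects and controllable batch effects, applies batch-effect
    correction (quantile normalization, linear scaling, parametric
    empirical-Bayes location/scale adjustment), diagnoses and removes
    batch-dominated principal components with protein traceback, and
    benchmarks protein- and complex-level feature selectors (t-test,
    hypergeometric enrichment, and the rank-based network algorithms
    SNET and FSNET) against pseudo-complex ground truth using
    precision, recall and F-score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    sva,
    mclust,
    optparse
Config/testthat/edition: 3
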