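Package: dendrocut
Title: Automated Selection of the Number of Clusters in Hierarchical
    Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the number of clusters in agglomerative hierarchical
    clustering by analysing the dendrogram merge heights. Implements four
    automated cutoff rules (elbow/acceleration, maximum difference, modal
    jump-size threshold, and the gap statistic with a uniform reference
    distribution), two resampling consensus schemes (half-sample mixing and
    leave-one-out), a seeded Gaussian-cluster simulator, and an evaluation
    harness reporting success rates and conditional error sizes over
    replicated simulations. A command-line interface is provided for use on
    expression matrices and other numeric sample-by-feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biobase,
    optparse
Config/testthat/edition: 3
biocViews: Clustering, GeneExpression, Software
RoxygenNote: 7.3.3
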