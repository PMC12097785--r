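Package: netseg
Title: Functional Network Segregation and Brain-Behavior Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes functional brain-network segregation and related graph
    metrics (within/between-network connectivity, participation coefficient,
    modularity, Louvain community detection) from node time series, derives
    cognitive domain factor scores from a neuropsychological test battery via
    exploratory factor analysis, and relates network metrics to cognition with
    covariate-adjusted partial correlations and false-discovery-rate
    correction. Includes a synthetic-cohort generator with planted
    block-modular connectivity and a planted brain-behavior association so the
    full pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
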