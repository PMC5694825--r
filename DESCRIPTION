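Package: connectocast
Title: Predicting Long-Term Cognitive Impairment from Baseline Connectome
    Graph Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting long-term cancer-related cognitive
    impairment from pre-treatment resting-state functional connectomes.
    Binarizes region-by-region connectivity matrices to minimum connection
    density, computes nodal graph metrics (degree, clustering coefficient,
    betweenness centrality, participation coefficient) and a provincial /
    connector hub taxonomy, normalizes neuropsychological test scores
    against a control group and applies the ICCTF impairment criterion
    longitudinally, and trains nested recursive-feature-elimination random
    forest classifiers with hold-out evaluation (exact binomial test, ROC
    AUC, paired-bootstrap AUC comparison) plus random-forest regression of
    individual test scores. A seeded synthetic-cohort generator produces
    modular weighted networks with a planted clustering deficit and matched
    cognition trajectories so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    randomForest,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
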