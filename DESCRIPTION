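Package: vocalflock
Title: Vocal Learning and Social Integration Analysis for Small Parrot Flocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying open-ended vocal learning and
    social integration in small captive flocks of budgerigars. Generates
    synthetic flock experiments (frequency-modulated contact calls with
    ground-truth annotations, dyadic interaction logs, proximity snapshots),
    detects calls by optimized energy thresholding with a random-forest
    signal/noise filter, extracts a 17-dimensional spectro-temporal feature
    vector per call, embeds calls into a 2-D acoustic trait space, estimates
    kernel-density highest-density-region areas and density-weighted overlap
    statistics (vocal diversity change, plasticity, convergence), builds
    weighted 4-node social networks (proximity, affiliation, agonism) with
    density and strength metrics, and fits the corresponding generalized
    linear mixed model battery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmmTMB,
    jsonlite,
    lme4,
    lmerTest,
    MASS,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
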