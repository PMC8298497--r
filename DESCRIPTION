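Package: edsem
Title: Brain Network Topology and Latent Emotion Dysregulation via Multi-Group SEM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links nodal topology of resting-state functional brain networks to a
    latent emotion-dysregulation factor across diagnostic groups. Builds absolute
    Fisher-z connectivity matrices from parcellated BOLD time series, thresholds
    them into density-matched binary graphs, computes six nodal topology measures
    with density integration, and fits multi-group latent-variable structural
    equation models by maximum likelihood, comparing group-specific and shared
    regression models with chi-square difference tests under Benjamini-Hochberg
    false-discovery-rate control and Bonferroni-corrected pairwise post-hoc
    models. A synthetic-cohort generator reproduces the statistical structure of
    the target study design so the full pipeline can be exercised and validated
    without access to restricted data.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
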