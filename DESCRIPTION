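Package: chromdyn
Title: Chromatin-State Dynamics Across Gene Expression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learn multivariate Bernoulli hidden Markov models of chromatin
    states from binarized histone-mark and CTCF tracks over a differentiation
    time course, cluster gene expression time-courses into modules, attribute
    chromatin states to gene regions via a data-derived extension window, and
    quantify per-module chromatin-state enrichment and temporal dynamics with
    one-sample t-tests, rank-sum comparisons and -log10 summed-P dynamics
    scores. Includes a fully parameterised synthetic-data generator with
    planted chromatin states, expression archetypes and state-dynamics
    coupling so every stage of the pipeline can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
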