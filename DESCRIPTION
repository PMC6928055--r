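Package: gutcohort
Title: Cohort Comparison of Gut Microbiota Abundance Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for comparing gut microbial community profiles
    between two cohorts (for example tribal and urban populations) from 16S
    OTU or genus abundance tables. Implements per-sample alpha diversity
    (Shannon, Simpson, bias-corrected Chao1) with rank-sum group comparison,
    Jensen-Shannon ordination with partitioning-around-medoids clustering and
    Calinski-Harabasz model selection, Dirichlet-multinomial mixture
    enterotyping with Laplace-evidence model selection, bootstrap scoring of
    core taxa, LDA-effect-size differential abundance in the LEfSe style,
    metadata association statistics (White's permutation test, Kruskal-Wallis
    with eta-squared and Tukey-Kramer post hoc, binned trend summaries),
    randomization-null Spearman co-occurrence networks with a critical-r edge
    rule, and a stratified cross-validated classification harness with
    ROC/AUC. A seeded synthetic-cohort generator with planted core taxa,
    planted differential abundance, enterotype components and metadata links
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
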