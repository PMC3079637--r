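Package: qmascreen
Title: Quantile-Based Matrix Approximation for Quantitative Genetic
    Interaction Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores quantitative genetic interactions from double-mutant
    fitness matrices using a quantile-based rank-one multiplicative matrix
    approximation (QMA). Single-mutant fitness vectors are estimated from
    row and column quantiles of the fitness matrix; interactions are scored
    as residuals from a multiplicative (or minimum/maximum/scaled-epistasis)
    null model. Includes tools for cross-screen comparison (intersections,
    correlations, extreme-tail agreement, hypergeometric enrichment grids),
    rank-aggregation integration of multiple screens (minimum, maximum,
    product and Borda count), ROC-based evaluation (AUC, normalized partial
    AUC, early sensitivity), ternary reference-class matrices built from
    curated interaction edge lists, and a synthetic-screen generator with
    planted interactions for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
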