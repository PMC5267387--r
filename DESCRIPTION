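Package: frsd
Title: Exact and Approximate Pairwise Comparisons of Friedman Rank Sums
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Exact inference for pairwise comparisons of Friedman rank sums
    in randomized complete block designs.  Computes the exact discrete null
    distribution of the rank-sum difference D = Ri - Rj by generating-function
    combinatorics in arbitrary-precision integer arithmetic, exact and mid
    p-values, exact critical differences, the recommended large-sample
    approximations (normal with optional continuity correction, equicorrelated
    multivariate-normal maximum, Studentized range, chi-squared), Bonferroni
    adjusted one-to-many and all-pairs comparison tables, and exact p-values
    for incomplete designs whose blocks split into complete parts, via
    convolution of per-part distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
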