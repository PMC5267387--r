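# Seeded synthetic data: null rank matrices (independent uniform within-block
# permutations), optional midrank-tie injection, and the p-value uniformity
# summary under the overall null.  Randomness uses R's Mersenne-Twister
# generator through a locally scoped seed, so a given seed always reproduces
# the same matrices without disturbing the caller's RNG state.

#' Generate a null rank matrix
#'
#' Draws each of the `n` blocks as an independent uniform permutation of
#' `1..k`, the null model of the Friedman test.  With `tie_rate > 0`, each
#' block independently (with that probability) has one uniformly chosen
#' adjacent rank pair `(r, r + 1)` replaced by midranks `r + 0.5`, emulating
#' midrank ties without changing the block sum `k(k+1)/2`.
#'
#' @inheritParams count_compositions
#' @param seed Optional integer seed; the same seed gives the same matrix.
#' @param tie_rate Per-block probability of injecting one midrank tie, in
#'   `[0, 1)`.
#' @return An `n` by `k` numeric matrix of (mid)ranks.
#' @examples
#' generate_null(k = 5, n = 3, seed = 1)
#' @export
generate_null <- function(k, n, seed = NULL, tie_rate = 0) {
  check_design(k, n)
  if (!is.numeric(tie_rate) || length(tie_rate) != 1L || tie_rate < 0 ||
      tie_rate >= 1) {
    stop("`tie_rate` must be a single number in [0, 1)", call. = FALSE)
  }
  draw <- function() {
    m <- t(vapply(seq_len(n), function(i) sample.int(k), integer(k)))
    m <- matrix(as.numeric(m), nrow = n)
    if (tie_rate > 0) {
      for (i in seq_len(n)) {
        if (stats::runif(1) < tie_rate) {
          r <- sample.int(k - 1, 1)
          m[i, m[i, ] %in% c(r, r + 1)] <- r + 0.5
        }
      }
    }
    colnames(m) <- paste0("group", seq_len(k))
    m
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Uniformity of exact p-values under the overall null
#'
#' Generates one null rank matrix, computes the exact p-value of every
#' pairwise rank-sum difference, and summarises their distribution.  When
#' all null hypotheses are true, p-values of a continuous statistic are
#' uniform on (0, 1) with mean 1/2 and variance 1/12; the discrete exact
#' p-values approach this as `k` and `n` grow.  The Kolmogorov distance is
#' the maximum gap between the empirical distribution of `1 - p` and the
#' uniform diagonal.
#'
#' @inheritParams generate_null
#' @return A one-row tibble with `k`, `n`, `n_pairs`, `mean`, `variance`,
#'   `ks_distance`.
#' @examples
#' null_pvalue_uniformity(k = 10, n = 5, seed = 1)
#' @export
null_pvalue_uniformity <- function(k, n, seed = NULL, tie_rate = 0) {
  m <- generate_null(k, n, seed = seed, tie_rate = tie_rate)
  rs <- colSums(m)
  cmb <- utils::combn(k, 2)
  d <- abs(rs[cmb[1, ]] - rs[cmb[2, ]])
  # midrank ties can make d half-integer; use the tied mid-p path there
  den <- big_pow(k * (k - 1), n)
  uniq <- sort(unique(d))
  pu <- vapply(uniq, function(di) {
    if (di == floor(di)) pvalue_ge(di, k, n) else mid_pvalue(di, k, n)
  }, numeric(1))
  p <- pu[match(d, uniq)]
  u <- sort(1 - p)
  np <- length(p)
  ks <- max(abs(seq_len(np) / np - u), abs((seq_len(np) - 1) / np - u))
  tibble::tibble(k = k, n = n, n_pairs = np,
                 mean = mean(p), variance = stats::var(p), ks_distance = ks)
}
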