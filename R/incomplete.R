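# Exact p-values for incomplete designs whose blocks split into complete
# parts (k_t groups ranked in n_t blocks).  The parts are independent, so the
# signed difference distribution of the total D = sum_t D_t is the
# convolution of the per-part distributions; the folded (absolute-difference)
# p-value doubles the signed tail once at the end, exactly as in the complete
# case.

#' Specify the parts of an incomplete design
#'
#' @param k,n Integer vectors: groups present and number of blocks in each
#'   part (recycled to a common length).
#' @return A tibble with columns `k`, `n`, `max_d` (per-part support bound
#'   `n*(k-1)`).
#' @examples
#' design_parts(k = c(12, 10), n = c(9, 1))
#' @export
design_parts <- function(k, n) {
  grid <- vctrs_recycle(k, n)
  purrr::pwalk(grid, function(k, n) check_design(k, n))
  dplyr::mutate(grid, max_d = n * (k - 1))
}

as_parts <- function(parts) {
  if (is.data.frame(parts)) {
    if (!all(c("k", "n") %in% names(parts))) {
      stop("`parts` needs columns `k` and `n`", call. = FALSE)
    }
    parts <- parts[c("k", "n")]
  } else if (is.list(parts)) {
    if (length(parts) < 1) stop("`parts` must not be empty", call. = FALSE)
    parts <- do.call(rbind, lapply(parts, function(p) {
      if (length(p) != 2) stop("each part must be a (k, n) pair", call. = FALSE)
      data.frame(k = p[[1]], n = p[[2]])
    }))
  } else {
    stop("`parts` must be a data frame with columns k, n or a list of ",
         "(k, n) pairs", call. = FALSE)
  }
  if (nrow(parts) < 1) stop("`parts` must not be empty", call. = FALSE)
  purrr::pwalk(parts, function(k, n) check_design(k, n))
  parts
}

#' Exact p-value for an incomplete design by convolution of parts
#'
#' Exact two-sided p-value \eqn{P(|D| \ge |d|)} of a total rank-sum
#' difference accumulated over independent complete parts
#' \eqn{(k_t, n_t)}, computed by exact integer convolution of the per-part
#' signed distributions.  Both compared groups must be present in every
#' part.  A single part reduces exactly to [pvalue_ge()]; parts sharing a
#' common `k` merge exactly (convolution consistency).  Parts are processed
#' in increasing support width, which bounds intermediate vector sizes but
#' does not affect the result (convolution commutes).
#'
#' @param d Total rank-sum difference (integer; the sign is ignored, the
#'   p-value is for `|d|`), `|d| <= sum(n_t * (k_t - 1))`.
#' @param parts Part specification: a data frame with columns `k` and `n`
#'   (see [design_parts()]) or a list of `c(k, n)` pairs.
#' @return Single numeric exact p-value in (0, 1].
#' @examples
#' pvalue_parts(4, design_parts(k = 3, n = 2))             # = pvalue_ge(4, 3, 2)
#' pvalue_parts(46, design_parts(c(12, 10), c(9, 1)))      # 0.003 (3 dp)
#' @export
pvalue_parts <- function(d, parts) {
  rec <- exact_pvalue_parts(d, parts)
  rec$p_exact
}

#' @rdname pvalue_parts
#' @return `exact_pvalue_parts()` returns a one-row tibble with the p-value
#'   and its exact rational representation (`p_num`, `den` decimal strings).
#' @export
exact_pvalue_parts <- function(d, parts) {
  parts <- as_parts(parts)
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d != round(d)) {
    stop("`d` must be a single integer", call. = FALSE)
  }
  dmax <- sum(parts$n * (parts$k - 1))
  if (abs(d) > dmax) {
    stop("`d` must satisfy |d| <= sum(n_t*(k_t-1)) = ", dmax, call. = FALSE)
  }
  parts <- parts[order(parts$n * (parts$k - 1)), , drop = FALSE]
  d <- abs(d)
  if (d == 0) {
    den <- purrr::reduce(
      purrr::map2_chr(parts$k, parts$n, ~ big_pow(.x * (.x - 1), .y)),
      big_mul)
    return(tibble::tibble(d = 0, p_exact = 1, p_num = den, den = den))
  }
  tail <- cpp_parts_tail(d, as.integer(parts$k), as.integer(parts$n))
  num <- big_mul("2", tail$num)
  tibble::tibble(d = d,
                 p_exact = big_ratio(num, tail$den),
                 p_num = num, den = tail$den)
}
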