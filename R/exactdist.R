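# Exact null distribution of the Friedman rank-sum difference D = Ri - Rj.
#
# Under the null every within-block permutation of ranks 1..k is equally
# likely, so a single block contributes a difference t in {-(k-1), ..., k-1}
# with multiplicity k - |t| (and 0 at t = 0) out of k(k-1) ordered rank pairs.
# Over n independent blocks the counts are the n-fold convolution of that
# multiplicity vector; equivalently they are given by a generating-function
# composition formula evaluated in exact integer arithmetic.

check_design <- function(k, n) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k) || k < 2) {
    stop("`k` must be a single integer >= 2 (got ", format(k), ")", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != round(n) || n < 1) {
    stop("`n` must be a single integer >= 1 (got ", format(n), ")", call. = FALSE)
  }
  invisible(list(k = as.integer(k), n = as.integer(n)))
}

check_d <- function(d, k, n, signed = TRUE, half = FALSE) {
  dmax <- n * (k - 1)
  if (any(is.na(d))) stop("`d` must not contain NA", call. = FALSE)
  frac <- d - floor(d)
  ok_frac <- if (half) frac %in% c(0, 0.5) else frac == 0
  if (!all(ok_frac)) {
    stop("`d` must be ", if (half) "integer or integer + 0.5" else "integer",
         " valued (got ", toString(format(d[!ok_frac])), ")", call. = FALSE)
  }
  lo <- if (signed) -dmax else 0
  bad <- d < lo | d > dmax
  if (any(bad)) {
    stop("`d` must satisfy ", if (signed) paste0(lo, " <= d <= ", dmax)
         else paste0("0 <= d <= n*(k-1) = ", dmax),
         " (got ", toString(format(d[bad])), ")", call. = FALSE)
  }
  invisible(d)
}

# Exact tail count W(D >= d) over the signed support, as a decimal string.
tail_count <- function(d, k, n) {
  vapply(d, cpp_tail_count, character(1), k = k, n = n)
}

#' Number of rank configurations giving a rank-sum difference
#'
#' Counts the distinct ways, out of the \eqn{\{k(k-1)\}^n} equally likely
#' ordered within-block rank pairs, that a pairwise rank-sum difference
#' \eqn{D = d} can arise in `n` independent blocks of `k` ranked groups.
#' The count is symmetric in the sign of `d` and is computed exactly in
#' arbitrary-precision integer arithmetic, so it is returned as a decimal
#' string (counts overflow doubles already for moderate designs).
#'
#' @param d Integer rank-sum difference(s), `|d| <= n*(k-1)`.
#' @param k Number of groups (\eqn{\ge 2}).
#' @param n Number of blocks (\eqn{\ge 1}).
#'
#' @return Character vector of exact nonnegative integer counts.
#'
#' @examples
#' count_compositions(0, k = 3, n = 2)   # "10"
#' count_compositions(4, k = 3, n = 2)   # unique extreme configuration: "1"
#' @export
count_compositions <- function(d, k, n) {
  check_design(k, n)
  check_d(d, k, n, signed = TRUE)
  vapply(d, cpp_point_count, character(1), k = k, n = n)
}

#' Exact null distribution of the rank-sum difference
#'
#' Builds the full signed distribution of \eqn{D = R_i - R_j} under the
#' Friedman null by n-fold integer convolution of the per-block difference
#' multiplicity vector (\eqn{k - |t|} ways to realise a within-block
#' difference \eqn{t \ne 0}).  The convolution is an independent construction
#' from the composition-count formula and serves as its oracle.
#'
#' @inheritParams count_compositions
#'
#' @return A tibble of class `frsd_distribution` with columns `d` (signed
#'   support, `-n(k-1)` to `n(k-1)`), `count` (exact counts, decimal strings)
#'   and `prob` (counts divided by \eqn{\{k(k-1)\}^n}, as doubles).
#'
#' @examples
#' build_distribution(k = 3, n = 2)
#' @export
build_distribution <- function(k, n) {
  check_design(k, n)
  counts <- cpp_conv_counts(k, n)
  dmax <- n * (k - 1)
  total <- big_pow(k * (k - 1), n)
  out <- tibble::tibble(
    d = seq.int(-dmax, dmax),
    count = as.character(counts),
    prob = vapply(counts, big_ratio, numeric(1), den = total)
  )
  structure(out, k = k, n = n, total = total,
            class = c("frsd_distribution", class(out)))
}

#' One-sided exact p-value over the signed support
#'
#' Upper-tail probability \eqn{P(D \ge d)} of the signed rank-sum difference
#' distribution, for any integer `d` in `[-n(k-1), n(k-1)]`.  Computed from
#' exact integer tail counts; `pvalue_ge_signed(-n*(k-1), k, n)` is exactly 1.
#'
#' @inheritParams count_compositions
#' @return Numeric vector of exact tail probabilities.
#' @examples
#' pvalue_ge_signed(1, k = 3, n = 2)  # 13/36
#' @export
pvalue_ge_signed <- function(d, k, n) {
  check_design(k, n)
  check_d(d, k, n, signed = TRUE)
  den <- big_pow(k * (k - 1), n)
  unname(vapply(tail_count(d, k, n), big_ratio, numeric(1), den = den))
}

# folded tail numerator (denominator {k(k-1)}^n): 2*W(D>=d) for d >= 1,
# the full mass for d = 0, zero above the support
folded_tail_num <- function(d, k, n) {
  dmax <- n * (k - 1)
  vapply(d, function(di) {
    if (di > dmax) return("0")
    if (di <= 0) return(big_pow(k * (k - 1), n))
    big_mul("2", cpp_tail_count(di, k, n))
  }, character(1))
}

#' Exact two-sided p-value of an absolute rank-sum difference
#'
#' Exact p-value \eqn{P(D \ge |d|)} of the folded (absolute-difference)
#' distribution: twice the one-sided tail for \eqn{d \ge 1}, and exactly 1
#' at \eqn{d = 0} (where doubling would exceed unity).
#'
#' @param d Nonnegative integer difference(s), `0 <= d <= n*(k-1)`.
#' @inheritParams count_compositions
#' @return Numeric vector of exact p-values in (0, 1].
#' @examples
#' pvalue_ge(11, k = 5, n = 5)      # 0.0326 (4 dp)
#' pvalue_ge(0, k = 5, n = 5)       # exactly 1
#' pvalue_ge(20, k = 5, n = 5)      # 2 * (5 * 4)^-5
#' @export
pvalue_ge <- function(d, k, n) {
  check_design(k, n)
  check_d(d, k, n, signed = FALSE)
  den <- big_pow(k * (k - 1), n)
  unname(vapply(folded_tail_num(d, k, n), big_ratio, numeric(1), den = den))
}

#' Mid p-value of an absolute rank-sum difference
#'
#' Half the point probability of the observed difference plus the probability
#' of more extreme values, \eqn{P_{mid} = P(D = d)/2 + P(D > d)}, which is
#' less conservative than the exact p-value on a discrete support.  A
#' half-integer `d` (possible with midrank ties) is handled as the average of
#' the exact p-values of the two adjacent integers; the two definitions
#' coincide, but a tied `d` is not an exact frequency probability and is
#' flagged by attribute `ties`.
#'
#' @param d Nonnegative integer or integer + 0.5 difference(s).
#' @inheritParams count_compositions
#' @return Numeric vector of mid p-values, each `<=` the exact p-value at the
#'   same point.
#' @examples
#' mid_pvalue(1, k = 3, n = 2)       # 22/36
#' mid_pvalue(10.5, k = 5, n = 5)    # 0.0440 (4 dp), the tied mid p-value
#' @export
mid_pvalue <- function(d, k, n) {
  check_design(k, n)
  check_d(d, k, n, signed = FALSE, half = TRUE)
  den <- big_pow(k * (k - 1), n)
  f <- floor(d)
  num_lo <- folded_tail_num(f, k, n)
  num_hi <- folded_tail_num(f + 1, k, n)
  num2 <- vapply(seq_along(d), function(i) big_add(num_lo[i], num_hi[i]),
                 character(1))
  out <- unname(vapply(num2, big_ratio, numeric(1), den = big_mul("2", den)))
  attr(out, "ties") <- any(d != f)
  out
}

#' Exact p-value record for rank-sum differences
#'
#' Rich tabular version of [pvalue_ge()] / [mid_pvalue()]: one row per query
#' with the exact, mid and point probabilities both as doubles and as exact
#' rationals (decimal numerator strings over the common denominator
#' \eqn{\{k(k-1)\}^n}).  Half-integer differences (midrank ties) carry only a
#' mid p-value and are flagged in `ties`.
#'
#' @inheritParams mid_pvalue
#' @param digits Rounding used for the display columns `p_display`,
#'   `mid_display`; default 4 as in the reference tables.
#' @return A tibble with columns `d`, `k`, `n`, `p_exact`, `p_mid`, `p_point`,
#'   `p_num`, `mid_num2` (numerator of twice the mid p-value), `point_num`,
#'   `den`, `ties`, `p_display`, `mid_display`.
#' @examples
#' exact_pvalue(c(0, 11, 20), k = 5, n = 5)
#' @export
exact_pvalue <- function(d, k, n, digits = 4) {
  check_design(k, n)
  check_d(d, k, n, signed = FALSE, half = TRUE)
  den <- big_pow(k * (k - 1), n)
  tied <- d != floor(d)
  f <- floor(d)

  p_num <- folded_tail_num(f, k, n)
  p_hi <- folded_tail_num(f + 1, k, n)
  mid_num2 <- vapply(seq_along(d), function(i) big_add(p_num[i], p_hi[i]),
                     character(1))
  point_num <- vapply(seq_along(d), function(i) {
    if (tied[i]) "0" else big_sub(p_num[i], p_hi[i])
  }, character(1))

  p_exact <- ifelse(tied, NA_real_,
                    unname(vapply(p_num, big_ratio, numeric(1), den = den)))
  p_mid <- unname(vapply(mid_num2, big_ratio, numeric(1), den = big_mul("2", den)))
  p_point <- unname(vapply(point_num, big_ratio, numeric(1), den = den))

  tibble::tibble(
    d = d, k = k, n = n,
    p_exact = p_exact, p_mid = p_mid, p_point = p_point,
    p_num = unname(ifelse(tied, NA_character_, p_num)),
    mid_num2 = mid_num2, point_num = point_num, den = den,
    ties = tied,
    p_display = round(p_exact, digits),
    mid_display = round(p_mid, digits)
  )
}

# exact strict test m * p(d) < alpha decided in integer arithmetic:
# m * num * aden < anum * den  (num/den already the folded p-value)
cd_exact_ok <- function(d, k, n, m, arat, den) {
  num <- folded_tail_num(d, k, n)
  lhs <- big_mul(big_mul(big_str(m), num), arat$den)
  rhs <- big_mul(arat$num, den)
  big_lt(lhs, rhs)
}

cd_exact <- function(k, n, alpha, m) {
  arat <- alpha_rational(alpha)
  den <- big_pow(k * (k - 1), n)
  dmax <- n * (k - 1)
  if (!cd_exact_ok(dmax, k, n, m, arat, den)) {
    warning("no attainable critical difference: even d = n*(k-1) = ", dmax,
            " has adjusted p-value >= alpha", call. = FALSE)
    return(NA_integer_)
  }
  lo <- 1L
  hi <- as.integer(dmax)
  # p is non-increasing in d, so bisection on the smallest passing d is exact
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (cd_exact_ok(mid, k, n, m, arat, den)) hi <- mid else lo <- mid + 1L
  }
  lo
}

#' Critical difference in Friedman rank sums
#'
#' Smallest rank-sum difference declared significant at familywise level
#' `alpha`.  The exact method searches the discrete support by bisection for
#' the smallest `d` with Bonferroni-adjusted exact p-value strictly below
#' `alpha`, deciding every comparison in exact integer arithmetic.  The
#' approximate methods are the recommended large-sample critical differences,
#' each rounded up to the smallest integer not less than the calculated
#' value:
#' \describe{
#'   \item{normal}{\eqn{z_{\alpha/(2m)} \sqrt{nk(k+1)/6}} (two-sided normal
#'     quantile; `m` Bonferroni comparisons).}
#'   \item{mvn}{\eqn{m_{\alpha,k-1,\rho=1/2} \sqrt{nk(k+1)/6}} with the
#'     two-sided equicoordinate critical point of `k - 1` equicorrelated
#'     standard normals (many-one comparisons).}
#'   \item{range}{\eqn{q_{\alpha,k,\infty}/\sqrt{2} \cdot \sqrt{nk(k+1)/6}}
#'     with the Studentized range quantile (all-pairs comparisons).}
#'   \item{chisq}{\eqn{\sqrt{\chi^2_{\alpha,k-1}} \sqrt{nk(k+1)/6}}.}
#' }
#'
#' @inheritParams count_compositions
#' @param alpha Familywise significance level in (0, 1).
#' @param comparisons `"unadjusted"` (m = 1), `"one-control"` (m = k - 1) or
#'   `"all-pairs"` (m = k(k-1)/2); sets the Bonferroni multiplier for the
#'   exact and normal methods.  Ignored by `mvn`, `range` and `chisq`, whose
#'   familywise control is built into the reference distribution.
#' @param method One of `"exact"`, `"normal"`, `"mvn"`, `"range"`, `"chisq"`.
#' @param m Optional explicit number of comparisons, overriding `comparisons`
#'   (exact and normal methods only).
#'
#' @return A single integer critical difference, or `NA` with a warning when
#'   no difference in the support reaches significance (exact method).
#'
#' @examples
#' critical_difference(5, 5)                                  # 11
#' critical_difference(5, 5, comparisons = "one-control")     # 13
#' critical_difference(5, 5, comparisons = "all-pairs")       # 14
#' critical_difference(5, 5, method = "range")                # 14
#' @export
critical_difference <- function(k, n, alpha = 0.05,
                                comparisons = c("unadjusted", "one-control",
                                                "all-pairs"),
                                method = c("exact", "normal", "mvn", "range",
                                           "chisq"),
                                m = NULL) {
  check_design(k, n)
  comparisons <- match.arg(comparisons)
  method <- match.arg(method)
  if (is.null(m)) {
    m <- switch(comparisons, unadjusted = 1, `one-control` = k - 1,
                `all-pairs` = k * (k - 1) / 2)
  }
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("`m` must be a single integer >= 1", call. = FALSE)
  }
  switch(method,
    exact = cd_exact(k, n, alpha, m),
    normal = cd_normal(k, n, alpha, m),
    mvn = cd_mvn_max(k, n, alpha),
    range = cd_range(k, n, alpha),
    chisq = cd_chisq(k, n, alpha)
  )
}
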