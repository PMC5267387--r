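# Large-sample approximations for the rank-sum difference distribution and
# their critical differences.  All quantiles come from established numerical
# routines (qnorm, qtukey, qchisq); the equicorrelated multivariate-normal
# maximum is computed by deterministic one-dimensional quadrature over the
# shared latent factor, so every critical difference is reproducible
# bit-for-bit.

rsd_sd <- function(k, n) sqrt(n * k * (k + 1) / 6)

#' Null moments of the rank-sum difference
#'
#' Mean, variance and kurtosis of \eqn{D = R_i - R_j} under the Friedman
#' null: mean 0, variance \eqn{nk(k+1)/6}, and kurtosis
#' \eqn{3 - 3/(5n) - 12/(5nk) - 6/(5nk(k+1))} (Whitfield's formula), which is
#' below 3 for every finite `n` (thinner-than-normal tails) and tends to 3 as
#' `n` grows.
#'
#' @inheritParams count_compositions
#' @return A one-row tibble with columns `k`, `n`, `mean`, `variance`,
#'   `kurtosis`.
#' @examples
#' null_moments(5, 5)  # variance 25, kurtosis 2.776
#' @export
null_moments <- function(k, n) {
  check_design(k, n)
  tibble::tibble(
    k = k, n = n, mean = 0,
    variance = n * k * (k + 1) / 6,
    kurtosis = 3 - 3 / (5 * n) - 12 / (5 * n * k) - 6 / (5 * n * k * (k + 1))
  )
}

#' Fraction of correlated pairs of rank-sum differences
#'
#' Under the null, two rank-sum differences are correlated (correlation 1/2)
#' exactly when they share one group, and uncorrelated otherwise.  The
#' proportion of correlated pairs among all unordered pairs of distinct
#' differences is `4 / (k + 1)`.  `method = "enumerate"` counts shared-group
#' pairs among all \eqn{k(k-1)/2} differences by brute force instead of the
#' closed form.
#'
#' @inheritParams count_compositions
#' @param method `"closed-form"` (default) or `"enumerate"`.
#' @return A single numeric fraction in (0, 1].
#' @examples
#' correlated_pair_fraction(7)   # 1/2
#' correlated_pair_fraction(79)  # 1/20
#' @export
correlated_pair_fraction <- function(k, method = c("closed-form", "enumerate")) {
  method <- match.arg(method)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 3) {
    stop("`k` must be a single integer >= 3 (at least two differences must exist)",
         call. = FALSE)
  }
  if (method == "closed-form") return(4 / (k + 1))
  pairs <- utils::combn(k, 2)
  np <- ncol(pairs)
  shared <- 0L
  for (i in seq_len(np - 1)) {
    for (j in seq.int(i + 1, np)) {
      if (length(intersect(pairs[, i], pairs[, j])) == 1L) shared <- shared + 1L
    }
  }
  shared / choose(np, 2)
}

#' Normal-approximate p-value for a rank-sum difference
#'
#' Two-sided tail \eqn{2\{1 - \Phi((d - c)/\sqrt{nk(k+1)/6})\}} of the
#' asymptotic normal distribution of `d`, with continuity correction
#' `c = 0.5` (on) or `c = 0` (off); clipped to (0, 1].
#'
#' @param d Nonnegative difference(s) in rank sums.
#' @inheritParams count_compositions
#' @param continuity Apply the 0.5 continuity correction?
#' @return Numeric vector of approximate p-values.
#' @examples
#' pvalue_normal(11, 5, 5)                     # z = 2.2
#' pvalue_normal(11, 5, 5, continuity = TRUE)  # z = 2.1
#' @export
pvalue_normal <- function(d, k, n, continuity = FALSE) {
  check_design(k, n)
  if (any(d < 0)) stop("`d` must be nonnegative", call. = FALSE)
  cc <- if (continuity) 0.5 else 0
  pmin(1, 2 * pnorm((d - cc) / rsd_sd(k, n), lower.tail = FALSE))
}

#' Studentized-range approximate p-value for a rank-sum difference
#'
#' Upper tail of the range of `k` independent standard normals (Studentized
#' range with infinite degrees of freedom) at the standardized difference
#' \eqn{\sqrt{2}\, d / \sqrt{nk(k+1)/6}}; inherently a simultaneous all-pairs
#' p-value.
#'
#' @inheritParams pvalue_normal
#' @return Numeric vector of approximate familywise p-values.
#' @examples
#' pvalue_range(31, 11, 4)  # 0.038 (3 dp)
#' @export
pvalue_range <- function(d, k, n) {
  check_design(k, n)
  if (any(d < 0)) stop("`d` must be nonnegative", call. = FALSE)
  ptukey(sqrt(2) * d / rsd_sd(k, n), nmeans = k, df = Inf, lower.tail = FALSE)
}

#' Relative error of the normal approximation
#'
#' Percentage relative error
#' \eqn{R(d) = 100\{P_{normal}(d - c) - P_{exact}(d)\}/P_{exact}(d)} of the
#' normal p-value (with or without continuity correction) against the exact
#' p-value.  Negative values mean the normal approximation underestimates
#' the true p-value; in the far tail the normal overestimates small exact
#' p-values and the error is positive.
#'
#' @inheritParams pvalue_normal
#' @return Numeric vector of percentage errors.
#' @export
relative_error <- function(d, k, n, continuity = FALSE) {
  p_ex <- pvalue_ge(d, k, n)
  if (any(p_ex <= 0)) stop("exact p-value underflows; d is too extreme",
                           call. = FALSE)
  100 * (pvalue_normal(d, k, n, continuity) - p_ex) / p_ex
}

# Two-sided equicoordinate critical point of kk equally correlated (rho = 1/2)
# standard normals: P(max |X_i| <= q) = 1 - alpha.  With X_i = (Z0 + Z_i)/
# sqrt(2) the coordinates are conditionally independent given the shared
# factor Z0, giving a one-dimensional integral solved by quadrature.
mvn_max_quantile <- function(kk, alpha) {
  if (kk < 1) stop("`k` must be at least 2", call. = FALSE)
  coverage <- function(q) {
    integrate(function(z) {
      dnorm_z <- stats::dnorm(z)
      dnorm_z * (pnorm(q * sqrt(2) - z) - pnorm(-q * sqrt(2) - z))^kk
    }, -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-12)$value
  }
  f <- function(q) coverage(q) - (1 - alpha)
  lo <- qnorm(1 - alpha / 2) - 1e-3
  hi <- qnorm(1 - alpha / (2 * kk)) + 0.5
  root <- uniroot(f, c(lo, hi), tol = 1e-9, extendInt = "upX")
  root$root
}

cd_normal <- function(k, n, alpha, m) {
  ceiling(qnorm(1 - alpha / (2 * m)) * rsd_sd(k, n))
}

cd_mvn_max <- function(k, n, alpha) {
  ceiling(mvn_max_quantile(k - 1, alpha) * rsd_sd(k, n))
}

cd_range <- function(k, n, alpha) {
  ceiling(qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2) * rsd_sd(k, n))
}

cd_chisq <- function(k, n, alpha) {
  ceiling(sqrt(qchisq(1 - alpha, df = k - 1)) * rsd_sd(k, n))
}

#' Exact and approximate critical differences for a set of designs
#'
#' One row per design `(k, n)` with the unadjusted, one-to-many (1xN) and
#' all-pairs (NxN) critical differences: exact, normal (Bonferroni z),
#' equicorrelated multivariate-normal maximum, Studentized range and
#' chi-squared.  Approximate values use the ceiling convention (rounded up to
#' the smallest integer not less than the calculated value).  An approximate
#' critical difference can exceed the largest attainable difference
#' `max_d = n*(k-1)`, in which case no difference in the support is
#' significant by that method.
#'
#' @param k,n Integer vectors of design dimensions (recycled to a common
#'   length).
#' @param alpha Familywise significance level.
#' @param exact Also compute the exact critical differences (bisection with
#'   exact arithmetic)?  Large designs cost more; approximations are
#'   essentially free.
#' @return A tibble of class `frsd_cd_table` with columns `k`, `n`, `max_d`,
#'   `cd_exact`, `cd_normal`, `cd_exact_1xn`, `cd_normal_1xn`, `cd_mvn`,
#'   `cd_exact_nxn`, `cd_normal_nxn`, `cd_range`, `cd_chisq`.
#' @examples
#' cd_table(k = 5, n = 5, exact = FALSE)
#' @export
cd_table <- function(k, n, alpha = 0.05, exact = TRUE) {
  grid <- vctrs_recycle(k, n)
  rows <- purrr::pmap(grid, function(k, n) {
    check_design(k, n)
    tibble::tibble(
      k = k, n = n, max_d = n * (k - 1),
      cd_exact = if (exact) cd_exact(k, n, alpha, 1) else NA_integer_,
      cd_normal = cd_normal(k, n, alpha, 1),
      cd_exact_1xn = if (exact) cd_exact(k, n, alpha, k - 1) else NA_integer_,
      cd_normal_1xn = cd_normal(k, n, alpha, k - 1),
      cd_mvn = cd_mvn_max(k, n, alpha),
      cd_exact_nxn = if (exact) cd_exact(k, n, alpha, k * (k - 1) / 2)
                     else NA_integer_,
      cd_normal_nxn = cd_normal(k, n, alpha, k * (k - 1) / 2),
      cd_range = cd_range(k, n, alpha),
      cd_chisq = cd_chisq(k, n, alpha)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, alpha = alpha, class = c("frsd_cd_table", class(out)))
}

vctrs_recycle <- function(k, n) {
  len <- max(length(k), length(n))
  tibble::tibble(k = rep_len(k, len), n = rep_len(n, len))
}
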