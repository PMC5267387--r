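test_that("null moments follow the closed forms and the exact pmf", {
  nm <- null_moments(5, 5)
  expect_equal(nm$variance, 25)
  expect_equal(nm$kurtosis, 2.776)
  # each correction term vanishes as n grows
  expect_gt(null_moments(5, 1e6)$kurtosis, 3 - 1e-5)
  expect_lt(null_moments(5, 1e6)$kurtosis, 3)
  # cross-check variance and kurtosis against the exact pmf
  for (des in list(c(5, 5), c(4, 3), c(6, 2))) {
    k <- des[1]; n <- des[2]
    dist <- build_distribution(k, n)
    mu2 <- sum(dist$d^2 * dist$prob)
    mu4 <- sum(dist$d^4 * dist$prob)
    nm <- null_moments(k, n)
    expect_equal(mu2, nm$variance, tolerance = 1e-10)
    expect_equal(mu4 / mu2^2, nm$kurtosis, tolerance = 1e-10)
  }
})

test_that("correlated pair fraction equals brute-force shared-group counting", {
  expect_equal(correlated_pair_fraction(7), 1 / 2)
  expect_equal(correlated_pair_fraction(79), 1 / 20)
  expect_equal(correlated_pair_fraction(3), 1)
  for (k in 3:12) {
    expect_equal(correlated_pair_fraction(k, method = "enumerate"),
                 4 / (k + 1), info = paste("k =", k))
  }
  expect_error(correlated_pair_fraction(2), "k")
})

test_that("normal approximate p-values follow the two-sided z tail", {
  expect_equal(pvalue_normal(0, 5, 5), 1)
  expect_equal(pvalue_normal(11, 5, 5), 2 * pnorm(-2.2))
  expect_equal(pvalue_normal(11, 5, 5), 0.0278, tolerance = 2e-3)
  expect_equal(pvalue_normal(11, 5, 5, continuity = TRUE), 2 * pnorm(-2.1))
  expect_equal(pvalue_normal(11, 5, 5, continuity = TRUE), 0.0357,
               tolerance = 2e-3)
})

test_that("relative error diagnostic matches its definition and tail sign", {
  # z = 2.2 normal tail vs exact 0.0326: about -14.7%
  expect_equal(relative_error(11, 5, 5),
               100 * (2 * pnorm(-2.2) - pvalue_ge(11, 5, 5)) /
                 pvalue_ge(11, 5, 5))
  expect_equal(relative_error(11, 5, 5), -14.7, tolerance = 0.2)
  # far tail: the normal overestimates small exact p-values
  expect_gt(relative_error(80, 10, 10), 0)
})

test_that("normal and exact p-values converge as n grows at fixed deviate", {
  k <- 5
  ratio <- vapply(c(10, 100), function(n) {
    d <- round(2 * sqrt(n * k * (k + 1) / 6))
    pvalue_normal(d, k, n) / pvalue_ge(d, k, n)
  }, numeric(1))
  expect_lt(abs(ratio[2] - 1), abs(ratio[1] - 1))
  expect_lt(abs(ratio[2] - 1), 0.05)
})

test_that("approximate critical differences reproduce the reference designs", {
  expect_equal(critical_difference(5, 5, method = "normal"), 10)
  expect_equal(critical_difference(5, 5, method = "normal",
                                   comparisons = "all-pairs"), 15)
  expect_equal(critical_difference(25, 5, method = "normal",
                                   comparisons = "all-pairs"), 88)
  expect_equal(critical_difference(5, 5, method = "mvn"), 13)
  expect_equal(critical_difference(10, 5, method = "mvn"), 26)
  expect_equal(critical_difference(5, 5, method = "range"), 14)
  expect_equal(critical_difference(11, 4, method = "range"), 31)
  expect_equal(critical_difference(5, 5, method = "chisq"), 16)
  expect_equal(critical_difference(10, 5, method = "chisq"), 40)
})

test_that("k = 2 degeneracies: mvn and range reduce to the plain z interval", {
  for (n in c(4, 9)) {
    cd_n <- critical_difference(2, n, method = "normal")
    expect_equal(critical_difference(2, n, method = "mvn"), cd_n)
    expect_equal(critical_difference(2, n, method = "range"), cd_n)
  }
  # underlying quantile identity: q_{a,2,inf} = sqrt(2) z_{a/2}
  expect_equal(qtukey(0.95, 2, Inf), sqrt(2) * qnorm(0.975), tolerance = 1e-6)
})

test_that("chi-squared critical difference increases strictly with k", {
  cds <- vapply(3:12, function(k) critical_difference(k, 5, method = "chisq"),
                numeric(1))
  expect_true(all(diff(cds) > 0))
})

test_that("the equicoordinate mvn quantile is solved to tight tolerance", {
  q <- frsd:::mvn_max_quantile(4, 0.05)
  expect_equal(q, 2.441771, tolerance = 1e-5)
  # coverage at the root is 1 - alpha
  cov <- integrate(function(z) {
    dnorm(z) * (pnorm(q * sqrt(2) - z) - pnorm(-q * sqrt(2) - z))^4
  }, -Inf, Inf, rel.tol = 1e-12)$value
  expect_equal(cov, 0.95, tolerance = 1e-7)
})
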