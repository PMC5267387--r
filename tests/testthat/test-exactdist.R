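test_that("composition counts match the convolution oracle on the small grid", {
  for (i in seq_len(nrow(small_grid))) {
    k <- small_grid$k[i]; n <- small_grid$n[i]
    cnt <- oracle_counts(k, n)
    dmax <- n * (k - 1)
    got <- as.numeric(count_compositions(-dmax:dmax, k, n))
    expect_equal(got, cnt, info = sprintf("k=%d n=%d", k, n))
  }
})

test_that("worked small-design counts are exact", {
  expect_identical(count_compositions(0, 3, 2), "10")
  expect_identical(count_compositions(1, 3, 2), "4")
  expect_identical(count_compositions(4, 3, 2), "1")   # unique extreme
  expect_identical(count_compositions(-4, 3, 2), "1")  # symmetry
})

test_that("the built distribution satisfies its structural invariants", {
  for (des in list(c(3, 2), c(2, 1), c(5, 4), c(6, 6))) {
    k <- des[1]; n <- des[2]
    dist <- build_distribution(k, n)
    dmax <- n * (k - 1)
    expect_equal(nrow(dist), 2 * dmax + 1)
    cnt <- as.numeric(dist$count)
    expect_equal(cnt, rev(cnt))                       # symmetry
    expect_equal(sum(cnt), (k * (k - 1))^n)           # normalization
    expect_equal(cnt[1], 1)                           # count at -max(d)
    expect_equal(sum(dist$prob), 1, tolerance = 1e-12)
    # agrees entrywise with the composition-count formula
    expect_equal(cnt, as.numeric(count_compositions(dist$d, k, n)))
  }
  expect_equal(as.numeric(build_distribution(2, 1)$count), c(1, 0, 1))
})

test_that("single-sum and double-sum tail evaluations agree exactly", {
  for (i in seq_len(nrow(small_grid))) {
    k <- small_grid$k[i]; n <- small_grid$n[i]
    for (d in 0:(n * (k - 1))) {
      expect_identical(frsd:::cpp_tail_count(d, k, n),
                       frsd:::cpp_tail_count_triple(d, k, n),
                       info = sprintf("k=%d n=%d d=%d", k, n, d))
    }
  }
})

test_that("signed and folded p-values match the oracle exactly", {
  expect_equal(pvalue_ge_signed(1, 3, 2), 13 / 36)
  expect_equal(pvalue_ge_signed(0, 3, 2), 23 / 36)
  expect_equal(pvalue_ge_signed(-4, 3, 2), 1)
  for (des in list(c(3, 2), c(4, 3), c(6, 5))) {
    k <- des[1]; n <- des[2]
    dmax <- n * (k - 1)
    expect_equal(pvalue_ge(0:dmax, k, n),
                 vapply(0:dmax, oracle_pvalue_ge, numeric(1), k = k, n = n))
  }
})

test_that("folded p-value endpoints are exact", {
  expect_identical(pvalue_ge(0, 5, 5), 1)
  expect_identical(pvalue_ge(0, 7, 3), 1)
  expect_equal(pvalue_ge(20, 5, 5), 2 * (5 * 4)^-5)
  expect_equal(pvalue_ge(12, 7, 2), 2 * (7 * 6)^-2)
})

test_that("exact p-values are positive and non-increasing in d", {
  for (des in list(c(5, 5), c(4, 6), c(11, 4))) {
    k <- des[1]; n <- des[2]
    p <- pvalue_ge(0:(n * (k - 1)), k, n)
    expect_true(all(p > 0))
    expect_true(all(diff(p) <= 0))
  }
})

test_that("mid p-value lies below the exact p-value and matches its formula", {
  expect_equal(mid_pvalue(1, 3, 2), 22 / 36, ignore_attr = TRUE)  # (8/36)/2 + 18/36
  for (des in list(c(5, 5), c(4, 3))) {
    k <- des[1]; n <- des[2]
    dmax <- n * (k - 1)
    p <- pvalue_ge(1:dmax, k, n)
    m <- mid_pvalue(1:dmax, k, n)
    expect_true(all(m < p))
    # half-integer mid p equals the mean of the adjacent exact p-values
    half <- mid_pvalue(seq(0.5, dmax - 0.5), k, n)
    adj <- (pvalue_ge(0:(dmax - 1), k, n) + pvalue_ge(1:dmax, k, n)) / 2
    expect_equal(as.numeric(half), adj)
  }
})

test_that("exact pmf moments are 0, nk(k+1)/6, 0 and Whitfield's kurtosis", {
  bm <- function(a, b) frsd:::big_mul(a, b)
  for (i in seq_len(nrow(small_grid))) {
    k <- small_grid$k[i]; n <- small_grid$n[i]
    dist <- build_distribution(k, n)
    d <- dist$d
    cnt <- as.numeric(dist$count)  # exact for k,n <= 6
    total <- (k * (k - 1))^n
    expect_equal(sum(d * cnt), 0)
    expect_equal(sum(d^3 * cnt), 0)
    expect_equal(sum(d^2 * cnt), total * n * k * (k + 1) / 6)
    # kurtosis identity in exact integers:
    # 180 * sum(d^4 c) == total * nk(k+1) * (15nk(k+1) - 3k(k+1) - 12(k+1) - 6)
    s4 <- Reduce(frsd:::big_add, Map(function(di, ci) {
      bm(frsd:::big_str(di^4), frsd:::big_str(ci))
    }, d, cnt), "0")
    lhs <- bm("180", s4)
    v <- n * k * (k + 1)
    rhs <- bm(frsd:::big_str(total),
              bm(frsd:::big_str(v),
                 frsd:::big_str(15 * v - 3 * k * (k + 1) - 12 * (k + 1) - 6)))
    expect_identical(lhs, rhs, info = sprintf("k=%d n=%d", k, n))
  }
})

test_that("exact critical differences bound the Type-I error below alpha", {
  for (k in c(5, 10)) {
    for (n in c(5, 10)) {
      cd <- critical_difference(k, n, alpha = 0.05)
      expect_lt(pvalue_ge(cd, k, n), 0.05)
      expect_gte(pvalue_ge(cd - 1, k, n), 0.05)
    }
  }
})

test_that("an unattainable critical difference is signalled", {
  expect_warning(cd <- critical_difference(2, 1), "no attainable")
  expect_true(is.na(cd))
  # k=2, n=1: the only positive difference has p = 1
  expect_identical(pvalue_ge(1, 2, 1), 1)
})

test_that("domain violations raise errors naming the violated bound", {
  expect_error(count_compositions(0, 1, 5), "k")
  expect_error(count_compositions(0, 3, 0), "n")
  expect_error(count_compositions(9, 3, 2), "d")
  expect_error(pvalue_ge(-1, 5, 5), "d")
  expect_error(pvalue_ge(2.3, 5, 5), "integer")
  expect_error(mid_pvalue(2.25, 5, 5), "integer")
  expect_error(critical_difference(5, 5, alpha = 1.5), "alpha")
})

test_that("exact_pvalue records are internally consistent", {
  rec <- exact_pvalue(c(0, 5, 11, 10.5), 5, 5)
  expect_equal(rec$p_exact[1], 1)
  expect_true(is.na(rec$p_exact[4]) && rec$ties[4])
  expect_equal(rec$p_mid[4], mid_pvalue(10.5, 5, 5), ignore_attr = TRUE)
  # p_mid = p_exact - p_point / 2 for integer d
  expect_equal(rec$p_mid[2:3], rec$p_exact[2:3] - rec$p_point[2:3] / 2)
  expect_equal(rec$p_display[3], 0.0326)
})
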