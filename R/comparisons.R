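# Rank transformation, the Friedman omnibus statistic, and the pairwise
# comparison driver combining the exact and approximate engines.

#' Within-block rank transformation
#'
#' Ranks raw scores within each block (row), assigning 1..k from least to
#' greatest (`direction = "ascending"`, the default) or from greatest to
#' least.  Ties receive midranks (the average of the ranks they would
#' occupy), so every row still sums to \eqn{k(k+1)/2}.
#'
#' @param x Numeric matrix or data frame, blocks as rows and groups as
#'   columns.  Must be complete; route designs with missing cells to
#'   [pvalue_parts()].
#' @param direction `"ascending"` (rank 1 = smallest value) or
#'   `"descending"` (rank 1 = largest value, common when scores measure
#'   performance).
#' @return Numeric matrix of (mid)ranks with attribute `ties` indicating
#'   whether any block contains tied values.
#' @examples
#' rank_transform(rbind(c(2.1, 3.7, 9.9), c(5, 5, 1)))
#' @export
rank_transform <- function(x, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  x <- as_rank_input(x)
  if (anyNA(x)) {
    stop("missing cells are not allowed in a complete layout; ",
         "use the incomplete-design tools (pvalue_parts) instead",
         call. = FALSE)
  }
  sign <- if (direction == "ascending") 1 else -1
  r <- t(apply(x, 1, function(row) rank(sign * row)))
  dimnames(r) <- dimnames(x)
  attr(r, "ties") <- any(r != round(r)) ||
    any(apply(r, 1, function(row) anyDuplicated(row) > 0))
  r
}

as_rank_input <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix or data frame (blocks x groups)",
         call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("group", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) {
    stop("duplicate group labels: ",
         toString(unique(colnames(x)[duplicated(colnames(x))])), call. = FALSE)
  }
  x
}

#' Rank sums per group
#'
#' @param ranks Rank matrix as returned by [rank_transform()] (blocks as
#'   rows).
#' @return Named numeric vector of per-group rank sums \eqn{R_j}.
#' @export
rank_sums <- function(ranks) {
  colSums(as_rank_input(ranks))
}

#' Friedman rank-sum test
#'
#' Omnibus test that the k groups are sampled from identical distributions
#' within each block, via
#' \eqn{X_r^2 = \frac{12}{nk(k+1)} \sum_j \{R_j - n(k+1)/2\}^2}, referred to
#' its limiting chi-squared distribution with `k - 1` degrees of freedom.
#' The statistic is not tie-corrected; a warning is raised when midrank ties
#' are present.
#'
#' @param x Raw scores or ranks, blocks as rows.
#' @param ranked Set `TRUE` when `x` already holds within-block ranks.
#' @inheritParams rank_transform
#' @return Object of class `frsd_test`: a list with `statistic`, `df`,
#'   `p.value`, `rank_sums`, `k`, `n`, `ties`.  Has [tidy()] and [glance()]
#'   methods.
#' @examples
#' m <- rbind(c(1, 2, 3), c(2, 1, 3))
#' friedman_rank_test(m, ranked = TRUE)
#' @export
friedman_rank_test <- function(x, ranked = FALSE,
                               direction = c("ascending", "descending")) {
  r <- if (ranked) validate_rank_matrix(x) else rank_transform(x, direction)
  k <- ncol(r)
  n <- nrow(r)
  check_design(k, n)
  rs <- colSums(r)
  stat <- 12 / (n * k * (k + 1)) * sum((rs - n * (k + 1) / 2)^2)
  ties <- isTRUE(attr(r, "ties"))
  if (ties) {
    warning("tied ranks present; the omnibus statistic is not tie-corrected",
            call. = FALSE)
  }
  structure(
    list(statistic = stat, df = k - 1,
         p.value = pchisq(stat, df = k - 1, lower.tail = FALSE),
         rank_sums = rs, k = k, n = n, ties = ties),
    class = "frsd_test"
  )
}

validate_rank_matrix <- function(x) {
  x <- as_rank_input(x)
  if (anyNA(x)) {
    stop("missing cells are not allowed in a complete layout; ",
         "use the incomplete-design tools (pvalue_parts) instead",
         call. = FALSE)
  }
  k <- ncol(x)
  target <- k * (k + 1) / 2
  bad <- abs(rowSums(x) - target) > 1e-8
  if (any(bad)) {
    stop("rows ", toString(which(bad)), " are not within-block rankings of 1..",
         k, " (row sums must equal k(k+1)/2 = ", target, ")", call. = FALSE)
  }
  ties <- any(apply(x, 1, anyDuplicated) > 0)
  attr(x, "ties") <- ties
  x
}

#' @export
print.frsd_test <- function(x, digits = 4, ...) {
  cat("Friedman rank-sum test\n")
  cat(sprintf("  k = %d groups, n = %d blocks%s\n", x$k, x$n,
              if (x$ties) " (midrank ties present)" else ""))
  cat(sprintf("  X_r^2 = %s on %d df, asymptotic p = %s\n",
              format(x$statistic, digits = digits), x$df,
              format.pval(x$p.value, digits = digits)))
  invisible(x)
}

#' @rdname friedman_rank_test
#' @param x,... Method arguments.
#' @export
tidy.frsd_test <- function(x, ...) {
  tibble::tibble(
    group = names(x$rank_sums),
    rank_sum = unname(x$rank_sums),
    mean_rank = unname(x$rank_sums) / x$n
  )
}

#' @rdname friedman_rank_test
#' @export
glance.frsd_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 k = x$k, n = x$n, ties = x$ties)
}

#' Pairwise comparisons of Friedman rank sums
#'
#' Builds the post-hoc comparison table for all \eqn{k(k-1)/2} pairs
#' (`mode = "all-pairs"`) or the `k - 1` comparisons against a named control
#' (`mode = "one-control"`): absolute rank-sum difference `d`, exact p-value
#' (mid-p path for half-integer `d` arising from midrank ties), mid p-value,
#' two-sided normal and Studentized-range approximate p-values, Bonferroni
#' adjusted exact and normal p-values (capped at 1), and a significance flag
#' (adjusted exact p strictly below `alpha`).
#'
#' @param x Input data: a raw-score or rank matrix (blocks as rows), or a
#'   named numeric vector of rank sums (supply `n`).
#' @param mode `"all-pairs"` or `"one-control"`.
#' @param control Group label of the control; required for
#'   `mode = "one-control"`.
#' @param alpha Familywise significance level.
#' @param n Number of blocks; only needed (and allowed) when `x` is a vector
#'   of rank sums.
#' @param ranked Set `TRUE` when a matrix `x` already holds ranks.
#' @inheritParams rank_transform
#' @return A tibble of class `frsd_comparison` with one row per comparison
#'   and columns `group_a`, `group_b`, `d`, `p_exact`, `p_mid`, `p_normal`,
#'   `p_range`, `p_exact_adj`, `p_normal_adj`, `significant`.  Attributes
#'   `k`, `n`, `mode`, `m`, `alpha`, `control`, `ties`.
#' @examples
#' rs <- c(A = 7, B = 10, C = 17, D = 18, E = 22)
#' pairwise_compare(rs, n = 4)
#' @export
pairwise_compare <- function(x, mode = c("all-pairs", "one-control"),
                             control = NULL, alpha = 0.05, n = NULL,
                             ranked = FALSE,
                             direction = c("ascending", "descending")) {
  mode <- match.arg(mode)
  if (is.matrix(x) || is.data.frame(x)) {
    if (!is.null(n)) stop("`n` is inferred from a matrix input", call. = FALSE)
    r <- if (ranked) validate_rank_matrix(x) else rank_transform(x, direction)
    rs <- colSums(r)
    n <- nrow(r)
    ties <- isTRUE(attr(r, "ties"))
  } else if (is.numeric(x) && !is.null(names(x))) {
    if (is.null(n)) stop("supply `n` (number of blocks) with rank sums",
                         call. = FALSE)
    rs <- x
    ties <- any(rs != round(rs))
  } else {
    stop("`x` must be a blocks-by-groups matrix/data frame or a named vector ",
         "of rank sums", call. = FALSE)
  }
  k <- length(rs)
  check_design(k, n)
  if (anyDuplicated(names(rs))) {
    stop("duplicate group labels: ",
         toString(names(rs)[duplicated(names(rs))]), call. = FALSE)
  }

  if (mode == "one-control") {
    if (is.null(control)) stop("`control` is required for one-control mode",
                               call. = FALSE)
    if (!control %in% names(rs)) {
      stop("unknown control group '", control, "'", call. = FALSE)
    }
    others <- setdiff(names(rs), control)
    pairs <- tibble::tibble(group_a = control, group_b = others)
    m <- k - 1
  } else {
    cmb <- utils::combn(names(rs), 2)
    pairs <- tibble::tibble(group_a = cmb[1, ], group_b = cmb[2, ])
    m <- k * (k - 1) / 2
  }

  d <- abs(rs[pairs$group_a] - rs[pairs$group_b])
  rec <- exact_pvalue(unname(d), k, n)
  # half-integer d (midrank ties): report the tied mid p-value as p_exact
  p_exact <- ifelse(rec$ties, rec$p_mid, rec$p_exact)
  p_normal <- pvalue_normal(unname(d), k, n)
  p_range <- pvalue_range(unname(d), k, n)

  out <- dplyr::mutate(
    pairs,
    d = unname(d),
    p_exact = p_exact,
    p_mid = rec$p_mid,
    p_normal = p_normal,
    p_range = p_range,
    p_exact_adj = pmin(1, m * p_exact),
    p_normal_adj = pmin(1, m * p_normal),
    significant = .data$p_exact_adj < alpha
  )
  structure(out, k = k, n = n, mode = mode, m = m, alpha = alpha,
            control = control, ties = ties,
            class = c("frsd_comparison", class(out)))
}

#' @rdname pairwise_compare
#' @export
glance.frsd_comparison <- function(x, ...) {
  tibble::tibble(
    k = attr(x, "k"), n = attr(x, "n"), mode = attr(x, "mode"),
    m = attr(x, "m"), alpha = attr(x, "alpha"),
    n_significant = sum(x$significant)
  )
}
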