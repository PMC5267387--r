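# ggplot2 visualisations for the package result types.

#' Plot the exact null distribution
#'
#' Needle plot of the exact point probabilities of the signed rank-sum
#' difference, with the exact upper-tail p-value overlaid as a step line.
#'
#' @param object A `frsd_distribution` from [build_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frsd_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$tail <- rev(cumsum(rev(df$prob)))
  k <- attr(object, "k")
  n <- attr(object, "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$d, y = 0,
                                       yend = .data$prob),
                          colour = "grey30") +
    ggplot2::geom_step(ggplot2::aes(y = .data$tail), colour = "steelblue") +
    ggplot2::labs(
      x = "rank sum difference d",
      y = "probability",
      title = sprintf("Exact null distribution of D (k = %d, n = %d)", k, n),
      subtitle = "needles: P(D = d); step: one-sided tail P(D ≥ d)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise comparison table
#'
#' Tile map of Bonferroni-adjusted exact p-values for every compared pair,
#' with significant pairs (adjusted p below the familywise level) outlined.
#'
#' @param object A `frsd_comparison` from [pairwise_compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frsd_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  alpha <- attr(object, "alpha")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group_a, y = .data$group_b,
                                   fill = .data$p_exact_adj)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$significant, , drop = FALSE],
                       fill = NA, colour = "red", linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$p_exact_adj)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "tomato", high = "white",
                                 limits = c(0, 1), name = "adjusted p") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Bonferroni-adjusted exact p-values",
                  subtitle = sprintf("outlined: significant at familywise alpha = %g",
                                     alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot exact versus approximate critical differences
#'
#' Dot plot comparing the critical differences of each method across the
#' designs in a [cd_table()].
#'
#' @param object A `frsd_cd_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frsd_cd_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(df, dplyr::starts_with("cd_"),
                              names_to = "method", values_to = "cd")
  long$design <- sprintf("k=%d, n=%d", long$k, long$n)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$design, y = .data$cd,
                                     colour = .data$method)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = NULL, y = "critical difference",
                  title = "Critical differences by method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
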