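# ggplot2 visualizations for the main result types.

#' Plot peak distribution across genome bins
#'
#' Side-by-side bars of the fraction of the genome vs the fraction of peaks
#' falling in each feature bin, mirroring the stacked-composition view used
#' for peak-annotation figures.
#'
#' @param dist Output of [peak_bin_distribution()].
#' @return A ggplot object.
#' @export
plot_bin_distribution <- function(dist) {
  long <- dist |>
    dplyr::select("bin", genome = "genome_fraction", peaks = "peak_fraction") |>
    tidyr::pivot_longer(c("genome", "peaks"), names_to = "what",
                        values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$fraction,
                                     fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot expression by gene class
#'
#' Boxplots of per-gene expression (log2 mean CPM + 1) for the two classes
#' of an expression comparison.
#'
#' @param cmp An `expr_class_comparison` from
#'   [compare_expression_by_class()].
#' @return A ggplot object.
#' @export
plot_expression_by_class <- function(cmp) {
  stopifnot(inherits(cmp, "expr_class_comparison"))
  ggplot2::ggplot(cmp$values, ggplot2::aes(x = .data$class, y = .data$expression)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "expression, log2(mean CPM + 1)",
                  subtitle = sprintf("rank-sum two-sided p = %.3g", cmp$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot domain length distribution
#'
#' @param domains Output of [call_domains()].
#' @return A ggplot object.
#' @export
plot_domain_lengths <- function(domains) {
  domains <- as_intervals(domains)
  ggplot2::ggplot(tibble(length = domains$end - domains$start),
                  ggplot2::aes(x = .data$length / 1000)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "domain length (kb)", y = "domains") +
    ggplot2::theme_minimal()
}
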