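#' Volcano plot of one or more comparisons
#'
#' log2 expression ratio against `-log10(FDR)`, DEGs coloured by
#' direction, with the ratio and FDR thresholds drawn as reference lines.
#'
#' @param results A `deg_result`.
#' @param fdr_max,min_abs_log2 Threshold lines, defaults matching
#'   [call_degs()].
#' @return A ggplot object, faceted by comparison.
#' @export
plot_volcano <- function(results, fdr_max = 0.001, min_abs_log2 = 1) {
  df <- as_tibble(results) %>%
    mutate(neglog_fdr = -log10(pmax(.data$fdr, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_ratio,
                                   y = .data$neglog_fdr,
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-min_abs_log2, min_abs_log2),
                        linetype = "dashed", colour = "blue") +
    ggplot2::geom_hline(yintercept = -log10(fdr_max),
                        linetype = "dashed", colour = "orange") +
    ggplot2::scale_colour_manual(values = c(up = "red", down = "darkgreen",
                                            none = "grey40")) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "log2 expression ratio", y = "-log10(FDR)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.deg_result <- function(object, ...) plot_volcano(object, ...)

#' Degree distribution of a projection network on log-log axes
#'
#' @param net A `projection_network`.
#' @return A ggplot object (positive degrees only).
#' @export
plot_degree_distribution <- function(net) {
  h <- network_stats(net)$degree_histogram %>% filter(.data$degree > 0)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$degree, y = .data$n_nodes)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "number of nodes",
                  title = igraph::graph_attr(net, "name")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.projection_network <- function(object, ...) {
  plot_degree_distribution(object)
}

#' Category composition bar chart
#'
#' @param assignments A `category_assignment`.
#' @return A ggplot object of category totals (excluded genes shown too).
#' @export
plot_categories <- function(assignments) {
  ggplot2::ggplot(category_totals(assignments),
                  ggplot2::aes(x = .data$category, y = .data$n,
                               fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
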