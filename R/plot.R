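#' Plot the top-ranked nodes of a centrality result
#'
#' Lollipop chart of the highest-scoring nodes, ranked top-down.
#'
#' @param object A `centrality_result`.
#' @param top How many nodes to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(contribution_centrality(load_fixture("florentine")), top = 10)
#' @export
autoplot.centrality_result <- function(object, top = 20L, ...) {
  df <- utils::head(rank_centrality(object), top)
  df$node <- factor(df$node, levels = rev(df$node))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$node)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$score,
                                       yend = .data$node),
                          colour = "grey60") +
    ggplot2::geom_point(size = 2.5, colour = "#2c7fb8") +
    ggplot2::labs(
      x = "centrality score", y = NULL,
      title = paste0(object$method, " centrality"),
      subtitle = if (!is.na(object$measure)) {
        paste0("measure = ", object$measure, ", convention = ",
               object$convention)
      }
    ) +
    ggplot2::theme_minimal()
}

#' Plot the pairwise rank agreement of a comparison
#'
#' Heatmap of Kendall tau-b correlations between every pair of compared
#' measures.
#'
#' @param object A `centrality_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.centrality_comparison <- function(object, ...) {
  ggplot2::ggplot(object$tau,
                  ggplot2::aes(x = .data$method1, y = .data$method2,
                               fill = .data$tau)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$tau)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#b2182b",
                                  mid = "white", high = "#2166ac") +
    ggplot2::labs(x = NULL, y = NULL, fill = "tau-b",
                  title = "Rank agreement between centrality measures") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Histogram of a centrality score distribution
#'
#' Column chart of the binned normalised scores from
#' [score_distribution()].
#'
#' @param result A `centrality_result`.
#' @param bins Number of bins.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(result, bins = 10L) {
  df <- score_distribution(result, bins)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                   y = .data$count)) +
    ggplot2::geom_col(width = 1 / bins, fill = "#2c7fb8",
                      colour = "white") +
    ggplot2::labs(x = "score / max score", y = "nodes",
                  title = paste0(result$method,
                                 " centrality score distribution")) +
    ggplot2::theme_minimal()
}
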