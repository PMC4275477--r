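#' Plot the score profile of a search result
#'
#' Relevance scores of the ranked hits, a quick view of how sharply the
#' ranking separates perfect matches (score 100) from partial ones.
#'
#' @param object A `search_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.search_result <- function(object, ...) {
  ggplot2::ggplot(object$hits, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(
      x = "Rank", y = "Relevance score",
      title = sprintf("\"%s\" (%s, %s): %d hits", object$query_text,
                      object$strategy, object$ranking, object$total_hits)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-query precision cells by strategy
#'
#' Strict and relaxed precision of every (query, strategy) cell, faceted by
#' mode, the standard comparison view for retrieval strategies.
#'
#' @param cells Precision-cell tibble from [precision_cells()] or
#'   [benchmark_tables()]`$precision`.
#' @return A ggplot object.
#' @export
plot_precision_cells <- function(cells) {
  long <- cells |>
    dplyr::filter(.data$retrieved > 0L) |>
    dplyr::mutate(
      strict = .data$relevant_strict / .data$retrieved,
      relaxed = .data$relevant_relaxed / .data$retrieved
    ) |>
    tidyr::pivot_longer(c("strict", "relaxed"), names_to = "mode",
                        values_to = "precision")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strategy, y = .data$precision)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~mode) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Precision over the first 20 citations") +
    ggplot2::theme_minimal()
}

#' Plot coverage totals by strategy
#'
#' @param coverage Tibble with a `query` column and one column of per-query
#'   totals per strategy (as returned in [benchmark_tables()]`$coverage`).
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage) {
  long <- coverage |>
    tidyr::pivot_longer(-"query", names_to = "strategy", values_to = "total")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strategy, y = .data$total)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Citations retrieved per query (log scale)") +
    ggplot2::theme_minimal()
}
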