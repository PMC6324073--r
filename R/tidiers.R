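#' Tidy a batch enrichment report
#'
#' @param x A `batch_report` from [batch_search()].
#' @param ... Unused.
#' @return The per-term results tibble (`category`, `term_id`, `k`, `K`,
#'   `n`, `N`, `p_value`, `adjusted_p`).
#' @method tidy batch_report
#' @export
tidy.batch_report <- function(x, ...) {
  tibble::as_tibble(x$results)
}

#' Summarise a batch enrichment report
#'
#' @param x A `batch_report` from [batch_search()].
#' @param ... Unused.
#' @param alpha Significance level applied to `adjusted_p` for the
#'   `n_significant` count.
#' @return One-row tibble: query sizes, terms tested, significant terms,
#'   smallest adjusted p-value.
#' @method glance batch_report
#' @export
glance.batch_report <- function(x, ..., alpha = 0.05) {
  tibble::tibble(
    n_query = length(x$query$resolved),
    n_unresolved = length(x$query$unresolved),
    n_terms_tested = nrow(x$results),
    n_significant = sum(x$results$adjusted_p <= alpha),
    min_adjusted_p = if (nrow(x$results)) min(x$results$adjusted_p)
                     else NA_real_
  )
}

#' Tidy a bipartite association graph
#'
#' @param x A `bipartite_graph` from [build_graph()].
#' @param ... Unused.
#' @return The edge tibble (`target_id`, `disease_id`, `overall`,
#'   `n_evidence`).
#' @method tidy bipartite_graph
#' @export
tidy.bipartite_graph <- function(x, ...) {
  tibble::as_tibble(x$edges)
}

#' Summarise a bipartite association graph
#'
#' @param x A `bipartite_graph` from [build_graph()].
#' @param ... Unused.
#' @return One-row tibble of vertex/edge counts, thresholds and the median
#'   retained overall score.
#' @method glance bipartite_graph
#' @export
glance.bipartite_graph <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x$edges),
    n_targets = length(x$target_neighbors),
    n_diseases = length(x$disease_neighbors),
    min_evidence = x$thresholds[["min_evidence"]],
    min_score = x$thresholds[["min_score"]],
    median_overall = if (nrow(x$edges)) stats::median(x$edges$overall)
                     else NA_real_
  )
}

#' Plot a batch enrichment report
#'
#' Lollipop chart of `-log10(adjusted p)` for the strongest terms, faceted
#' by annotation category.
#'
#' @param object A `batch_report`.
#' @param top Terms shown per category.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot batch_report
#' @export
autoplot.batch_report <- function(object, top = 10, ...) {
  df <- tibble::as_tibble(object$results) |>
    dplyr::group_by(.data$category) |>
    dplyr::slice_min(.data$adjusted_p, n = top, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(term_id = stats::reorder(.data$term_id,
                                           -log10(.data$adjusted_p)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$adjusted_p),
                                   y = .data$term_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0,
                                       xend = -log10(.data$adjusted_p),
                                       yend = .data$term_id),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$k), colour = "#2166ac") +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free_y") +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
                  size = "overlap") +
    ggplot2::theme_minimal()
}

#' Plot a similar-entity ranking
#'
#' @param object A `similar_entities` tibble from [similar_entities()].
#' @param ... Unused.
#' @return A ggplot object: relationship scores of the ranked neighbors.
#' @method autoplot similar_entities
#' @export
autoplot.similar_entities <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(entity_b = stats::reorder(.data$entity_b, .data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$entity_b)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "relationship score", y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot an association score landscape
#'
#' Top target-disease pairs by overall association score.
#'
#' @param object A `tr_associations` tibble from
#'   [aggregate_associations()].
#' @param top Pairs shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tr_associations
#' @export
autoplot.tr_associations <- function(object, top = 20, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::slice_max(.data$overall, n = top, with_ties = FALSE) |>
    dplyr::mutate(pair = stats::reorder(paste(.data$target_id, .data$disease_id,
                                              sep = " / "), .data$overall))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overall, y = .data$pair)) +
    ggplot2::geom_col(fill = "#762a83") +
    ggplot2::labs(x = "overall association score", y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}
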