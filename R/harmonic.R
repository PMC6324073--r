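#' Harmonic-sum aggregation settings
#'
#' The rank-discounted sum used at every aggregation level. With
#' normalization on, singleton and constant score vectors are fixed points
#' and the result stays in `[0, 1]`.
#'
#' @param exponent Positive exponent of the rank denominator (default 2).
#' @param cap Maximum number of terms summed (default 100), so unboundedly
#'   deep sources such as text mining cannot accumulate without limit.
#' @param normalize Divide by the same-length truncated maximum
#'   `sum(1 / i^exponent)` (default `TRUE`).
#' @param overall_from Whether the overall association score aggregates the
#'   data-source scores (`"sources"`, default) or the data-type scores.
#' @return A `harmonic_config` list.
#' @export
harmonic_config <- function(exponent = 2, cap = 100L, normalize = TRUE,
                            overall_from = c("sources", "types")) {
  if (!(is.numeric(exponent) && exponent > 0)) {
    stop("domain error: exponent must be positive", call. = FALSE)
  }
  if (!(is.numeric(cap) && cap >= 1)) {
    stop("domain error: cap must be at least 1", call. = FALSE)
  }
  structure(list(exponent = exponent, cap = as.integer(cap),
                 normalize = normalize,
                 overall_from = match.arg(overall_from)),
            class = "harmonic_config")
}

#' Harmonic sum of unit-interval scores
#'
#' Sorts the scores descending and computes
#' `sum(s[i] / i^exponent)` over the first `min(n, cap)` ranks, divided (when
#' `normalize` is on) by its maximum `sum(1 / i^exponent)` over the same
#' ranks. Permutation-invariant, monotone non-decreasing in every element;
#' an empty input scores 0.
#'
#' @param scores Numeric vector of values in `[0, 1]`.
#' @param config A [harmonic_config()].
#' @return A single non-negative number; in `[0, 1]` when normalized.
#' @examples
#' harmonic_sum(c(1, 0.5))  # (1 + 0.5/4) / (1 + 1/4) = 0.9
#' @export
harmonic_sum <- function(scores, config = harmonic_config()) {
  if (length(scores) == 0L) return(0)
  if (!is.numeric(scores) || any(scores < 0 | scores > 1)) {
    stop("domain error: scores must lie in [0, 1]", call. = FALSE)
  }
  s <- sort(scores, decreasing = TRUE)
  i <- seq_len(min(length(s), config$cap))
  w <- i^(-config$exponent)
  raw <- sum(s[i] * w)
  if (config$normalize) raw / sum(w) else raw
}

#' Aggregate scored evidence into association records
#'
#' Groups evidence by (target, disease) and rolls scores up three levels:
#' the data-source score is the harmonic sum of that source's evidence
#' scores; the data-type score is the harmonic sum of its sources' scores;
#' the overall association score is the harmonic sum of the data-source
#' scores (or of the type scores, per `config$overall_from`).
#'
#' @param evidence Scored evidence tibble (every row must carry a score; see
#'   [score_evidence()]).
#' @param registry Data-source registry.
#' @param config A [harmonic_config()].
#' @return A `tr_associations` tibble ordered lexicographically by
#'   `(target_id, disease_id)` with columns `target_id`, `disease_id`,
#'   `overall`, `n_evidence` and list-columns `source_scores`
#'   (`data_source`, `data_type`, `score`, `n_evidence`) and `type_scores`
#'   (`data_type`, `score`).
#' @examples
#' ev <- simulate_evidence(fixture_config(n_targets = 4, n_diseases = 3,
#'                                        seed = 1))
#' aggregate_associations(score_evidence(ev))
#' @export
aggregate_associations <- function(evidence, registry = default_registry(),
                                   config = harmonic_config()) {
  if (nrow(evidence) == 0L) {
    out <- tibble::tibble(target_id = character(), disease_id = character(),
                          overall = double(), n_evidence = integer(),
                          source_scores = list(), type_scores = list())
    class(out) <- c("tr_associations", class(out))
    return(out)
  }
  if (anyNA(evidence$score)) {
    stop("precondition error: evidence must be scored before aggregation",
         call. = FALSE)
  }
  entries <- registry_lookup(registry, evidence$data_source)
  evidence$data_type <- entries$data_type

  per_source <- evidence |>
    dplyr::group_by(.data$target_id, .data$disease_id, .data$data_source,
                    .data$data_type) |>
    dplyr::summarise(
      score = harmonic_sum(.data$score, config),
      n_evidence = dplyr::n(), .groups = "drop"
    )

  out <- per_source |>
    dplyr::group_by(.data$target_id, .data$disease_id) |>
    dplyr::group_modify(function(src, key) {
      typ <- src |>
        dplyr::group_by(.data$data_type) |>
        dplyr::summarise(score = harmonic_sum(.data$score, config),
                         .groups = "drop") |>
        dplyr::arrange(.data$data_type)
      overall_in <- if (config$overall_from == "sources") src$score
                    else typ$score
      tibble::tibble(
        overall = harmonic_sum(overall_in, config),
        n_evidence = sum(src$n_evidence),
        source_scores = list(dplyr::arrange(src, .data$data_source)),
        type_scores = list(typ)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$target_id, .data$disease_id)
  class(out) <- c("tr_associations", class(out))
  out
}
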