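#' Read evidence strings from JSON Lines
#'
#' Parses one evidence record per line. Each record carries `target_id`,
#' `disease_id`, `data_source`, an optional unit-interval `score` and a
#' `payload` object with the source-specific fields its scoring rule needs
#' (for example `p_value`, `n_cases`, `tier`, `precomputed_score`). Unknown
#' payload fields are preserved, not rejected.
#'
#' @param path Path to a JSON Lines file, or a character vector of lines.
#' @param registry Data-source registry (see [default_registry()]).
#' @param strict If `TRUE`, identifiers must follow the usual prefix
#'   conventions (`ENSG` targets; `EFO_`, `Orphanet_`, `HP_` or `MONDO_`
#'   diseases). Shape (non-empty string) is always enforced.
#' @return A tibble with columns `line`, `target_id`, `disease_id`,
#'   `data_source`, `data_type`, `score` (`NA` until scored) and a `payload`
#'   list-column, in input order.
#' @seealso [write_evidence()], [score_evidence()]
#' @export
read_evidence <- function(path, registry = default_registry(), strict = FALSE) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  keep <- which(nzchar(trimws(lines)))
  recs <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    ln <- keep[j]
    rec <- tryCatch(
      jsonlite::fromJSON(lines[ln], simplifyVector = TRUE),
      error = function(e) {
        stop(sprintf("parse error at line %d: %s", ln, conditionMessage(e)),
             call. = FALSE)
      }
    )
    recs[[j]] <- parse_evidence_record(rec, ln, registry, strict)
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      line = integer(), target_id = character(), disease_id = character(),
      data_source = character(), data_type = character(), score = double(),
      payload = list()
    )
  }
  out
}

parse_evidence_record <- function(rec, line, registry, strict) {
  for (f in c("target_id", "disease_id", "data_source")) {
    if (is.null(rec[[f]]) || !is.character(rec[[f]]) || !nzchar(rec[[f]])) {
      stop(sprintf("validation error at line %d: missing or empty field '%s'",
                   line, f), call. = FALSE)
    }
  }
  entry <- tryCatch(registry_lookup(registry, rec$data_source),
                    error = function(e) {
                      stop(sprintf("line %d: %s", line, conditionMessage(e)),
                           call. = FALSE)
                    })
  if (!is.null(rec$data_type) && !identical(rec$data_type, entry$data_type)) {
    stop(sprintf(
      "validation error at line %d: data_type '%s' is not the registry type '%s' for source '%s'",
      line, rec$data_type, entry$data_type, rec$data_source), call. = FALSE)
  }
  if (strict) check_identifier_prefixes(rec$target_id, rec$disease_id, line)
  payload <- rec$payload %||% list()
  if (!is.list(payload)) {
    stop(sprintf("validation error at line %d: payload must be an object", line),
         call. = FALSE)
  }
  check_payload(payload, entry$rule, line)
  score <- rec$score %||% NA_real_
  if (!is.na(score) && (!is.numeric(score) || score < 0 || score > 1)) {
    stop(sprintf("validation error at line %d: score %s outside [0, 1]",
                 line, format(score)), call. = FALSE)
  }
  tibble::tibble(
    line = as.integer(line),
    target_id = rec$target_id, disease_id = rec$disease_id,
    data_source = rec$data_source, data_type = entry$data_type,
    score = as.numeric(score), payload = list(payload)
  )
}

check_identifier_prefixes <- function(target_id, disease_id, line) {
  if (!grepl("^ENSG", target_id)) {
    stop(sprintf("validation error at line %d: target_id '%s' lacks ENSG prefix",
                 line, target_id), call. = FALSE)
  }
  if (!grepl("^(EFO_|Orphanet_|HP_|MONDO_)", disease_id)) {
    stop(sprintf(
      "validation error at line %d: disease_id '%s' lacks an ontology prefix",
      line, disease_id), call. = FALSE)
  }
  invisible(TRUE)
}

check_payload <- function(payload, rule, line = NA_integer_) {
  miss <- setdiff(required_payload_fields(rule), names(payload))
  if (length(miss)) {
    stop(sprintf(
      "validation error%s: payload field(s) %s required by rule '%s' are missing",
      if (is.na(line)) "" else sprintf(" at line %d", line),
      paste(sQuote(miss, q = FALSE), collapse = ", "), rule), call. = FALSE)
  }
  p <- payload$p_value
  if (!is.null(p) && (!is.numeric(p) || p <= 0 || p > 1)) {
    stop(sprintf(
      "validation error%s: payload field 'p_value' must lie in (0, 1]",
      if (is.na(line)) "" else sprintf(" at line %d", line)), call. = FALSE)
  }
  ps <- payload$precomputed_score
  if (!is.null(ps) && (!is.numeric(ps) || ps < 0 || ps > 1)) {
    stop(sprintf(
      "validation error%s: payload field 'precomputed_score' outside [0, 1]",
      if (is.na(line)) "" else sprintf(" at line %d", line)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write evidence strings to JSON Lines
#'
#' Inverse of [read_evidence()]: one JSON object per record, payload included
#' verbatim (so unknown payload fields round-trip).
#'
#' @param evidence Evidence tibble as returned by [read_evidence()] or
#'   [simulate_evidence()].
#' @param path Destination file.
#' @return Invisibly, the number of rows written.
#' @export
write_evidence <- function(evidence, path) {
  lines <- purrr::map_chr(seq_len(nrow(evidence)), function(i) {
    rec <- list(
      target_id = evidence$target_id[i],
      disease_id = evidence$disease_id[i],
      data_source = evidence$data_source[i],
      data_type = evidence$data_type[i],
      payload = evidence$payload[[i]]
    )
    if (!is.na(evidence$score[i])) rec$score <- evidence$score[i]
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  })
  writeLines(lines, path)
  invisible(length(lines))
}

#' Write association records to JSON Lines (and optional flat TSV)
#'
#' @param associations Association tibble from [aggregate_associations()].
#' @param path Destination JSON Lines file.
#' @param flat Optional path for a flat tab-separated export with one row per
#'   (pair, data source) and header
#'   `target_id, disease_id, datasource, datatype, score, overall`.
#' @return Invisibly, the number of JSON Lines rows written.
#' @export
write_associations <- function(associations, path, flat = NULL) {
  lines <- purrr::map_chr(seq_len(nrow(associations)), function(i) {
    src <- associations$source_scores[[i]]
    typ <- associations$type_scores[[i]]
    rec <- list(
      target_id = associations$target_id[i],
      disease_id = associations$disease_id[i],
      overall = associations$overall[i],
      n_evidence = associations$n_evidence[i],
      source_scores = stats::setNames(as.list(src$score), src$data_source),
      source_types = stats::setNames(as.list(src$data_type), src$data_source),
      evidence_counts = stats::setNames(as.list(src$n_evidence), src$data_source),
      type_scores = stats::setNames(as.list(typ$score), typ$data_type)
    )
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  if (!is.null(flat)) {
    flat_tbl <- associations |>
      dplyr::select("target_id", "disease_id", "overall", "source_scores") |>
      tidyr::unnest("source_scores") |>
      dplyr::transmute(
        target_id = .data$target_id, disease_id = .data$disease_id,
        datasource = .data$data_source, datatype = .data$data_type,
        score = .data$score, overall = .data$overall
      )
    utils::write.table(flat_tbl, flat, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(length(lines))
}

#' Read association records written by [write_associations()]
#'
#' @param path JSON Lines file of association records.
#' @return Association tibble in the shape produced by
#'   [aggregate_associations()].
#' @export
read_associations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::map(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    src <- tibble::tibble(
      data_source = names(rec$source_scores),
      data_type = as.character(unlist(rec$source_types)),
      score = as.numeric(unlist(rec$source_scores)),
      n_evidence = as.integer(unlist(rec$evidence_counts))
    )
    typ <- tibble::tibble(
      data_type = names(rec$type_scores),
      score = as.numeric(unlist(rec$type_scores))
    )
    tibble::tibble(
      target_id = rec$target_id, disease_id = rec$disease_id,
      overall = rec$overall, n_evidence = as.integer(rec$n_evidence),
      source_scores = list(src), type_scores = list(typ)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tr_associations", class(out))
  out
}
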