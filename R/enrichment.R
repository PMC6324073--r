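#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` members of a size-`K` annotation set when sampling `n` genes
#' without replacement from a universe of `N`.
#'
#' @param k Observed overlap count(s).
#' @param K Annotation-set size(s).
#' @param n Query-set size(s).
#' @param N Universe size(s).
#' @return Upper-tail probabilities; 1 when `k = 0`.
#' @examples
#' hypergeom_tail(4, 5, 4, 10)  # 5 / 210
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(K > N) || any(n > N) ||
      any(k > pmin(K, n))) {
    stop("domain error: need 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Upper-tail Poisson-binomial probability
#'
#' `P(X >= k)` for `X` the sum of independent Bernoulli trials with success
#' probabilities `probs`, computed by exact dynamic-programming convolution
#' of the count distribution. This is the pathway-alteration statistic:
#' `probs[j]` is the probability that sample `j` carries at least one
#' somatic mutation in the pathway and `k` the observed number of altered
#' samples.
#'
#' @param probs Per-trial success probabilities in `[0, 1]`.
#' @param k Threshold count, `0 <= k <= length(probs)`.
#' @return A single probability.
#' @seealso [pathway_alteration_prob()]
#' @export
poisson_binomial_tail <- function(probs, k) {
  if (length(probs) && (!is.numeric(probs) || any(probs < 0 | probs > 1))) {
    stop("domain error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (k < 0 || k > length(probs)) {
    stop("domain error: need 0 <= k <= length(probs)", call. = FALSE)
  }
  f <- 1  # f[j + 1] = P(X = j) after convolving each trial in turn
  for (p in probs) f <- c(f, 0) * (1 - p) + c(0, f) * p
  sum(f[seq.int(k + 1, length(f))])
}

#' Per-sample pathway alteration probability
#'
#' A pathway counts as altered in a sample as soon as one of its genes is
#' somatically mutated, so under independence the alteration probability is
#' `1 - prod(1 - q)` over the per-gene mutation probabilities `q`.
#'
#' @param q Per-gene mutation probabilities in `[0, 1]` for one sample.
#' @return A single probability.
#' @export
pathway_alteration_prob <- function(q) {
  if (length(q) && (!is.numeric(q) || any(q < 0 | q > 1))) {
    stop("domain error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  1 - prod(1 - q)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1, returned in the
#' original order.
#'
#' @param p_values Probabilities in `(0, 1]`.
#' @return Adjusted values, same length and order; empty in, empty out.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (!is.numeric(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("domain error: p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Construct and validate an annotation table
#'
#' @param sets Named list: term identifier to character vector of member
#'   genes.
#' @param universe Character vector of all genes considered; every set
#'   member must belong to it.
#' @param category One of `"disease"`, `"pathway"`, `"go"`, `"drug"`.
#' @return An `annotation_table` list.
#' @export
annotation_table <- function(sets, universe,
                             category = c("disease", "pathway", "go",
                                          "drug")) {
  category <- match.arg(category)
  universe <- unique(universe)
  sets <- lapply(sets, unique)
  stray <- setdiff(unique(unlist(sets, use.names = FALSE)), universe)
  if (length(stray)) {
    stop("validation error: set members outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(category = category, sets = sets, universe = universe),
            class = "annotation_table")
}

#' Read an annotation table from a two-column TSV
#'
#' Expects tab-separated `term_id`, `gene_id` pairs (header optional,
#' detected by name).
#'
#' @param path TSV file path.
#' @param category Annotation category.
#' @param universe Gene universe; defaults to all genes seen in the file.
#' @return An [annotation_table()].
#' @export
read_annotation_table <- function(path, category = "pathway",
                                  universe = NULL) {
  tbl <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("term_id", "gene_id"),
                           colClasses = "character")
  if (nrow(tbl) && identical(tolower(tbl$term_id[1]), "term_id")) {
    tbl <- tbl[-1, , drop = FALSE]
  }
  sets <- split(tbl$gene_id, tbl$term_id)
  annotation_table(sets, universe %||% unique(tbl$gene_id), category)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `term<TAB>description<TAB>gene...`.
#'
#' @inheritParams read_annotation_table
#' @return An [annotation_table()].
#' @export
read_gmt <- function(path, category = "pathway", universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop(sprintf("parse error at line %d: GMT rows need term, description and at least one gene",
                 bad[1]), call. = FALSE)
  }
  sets <- setNames(lapply(parts, function(x) x[-(1:2)]),
                   vapply(parts, `[[`, "", 1L))
  annotation_table(sets, universe %||% unique(unlist(sets, use.names = FALSE)),
                   category)
}

#' Resolve a raw target list into a batch query
#'
#' Collapses duplicates (with a warning counting them), resolves synonyms
#' against a local table and splits the list into resolved members of the
#' universe and unresolved leftovers. Lists longer than `max_targets`
#' (default 200, the batch-search limit) are rejected.
#'
#' @param ids Character vector of raw identifiers, or a path to a plain-text
#'   or CSV file with one identifier per line.
#' @param universe Gene universe the query is resolved against.
#' @param synonyms Optional data frame with columns `synonym`, `canonical`.
#' @param max_targets Hard limit on the raw list length.
#' @return A `batch_query` list: `raw`, `resolved`, `unresolved`,
#'   `n_duplicates`.
#' @export
batch_query <- function(ids, universe, synonyms = NULL, max_targets = 200) {
  if (length(ids) == 1L && file.exists(ids)) {
    ids <- utils::read.csv(ids, header = FALSE,
                           colClasses = "character")[[1]]
  }
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  if (length(ids) > max_targets) {
    stop(sprintf(
      "list-size error: %d identifiers submitted; the batch limit is %d targets",
      length(ids), max_targets), call. = FALSE)
  }
  n_dup <- length(ids) - length(unique(ids))
  if (n_dup > 0) {
    warning(sprintf("%d duplicate identifier(s) collapsed", n_dup),
            call. = FALSE)
  }
  ids <- unique(ids)
  resolved_ids <- ids
  if (!is.null(synonyms)) {
    m <- match(ids, synonyms$synonym)
    resolved_ids <- ifelse(is.na(m), ids, synonyms$canonical[m])
  }
  in_universe <- resolved_ids %in% universe
  structure(list(
    raw = ids,
    resolved = unique(resolved_ids[in_universe]),
    unresolved = ids[!in_universe],
    n_duplicates = n_dup
  ), class = "batch_query")
}

#' Batch enrichment search over annotation tables
#'
#' For each non-drug annotation table, every term overlapping the query by
#' at least one gene is tested with the upper-tail hypergeometric
#' probability, Benjamini-Hochberg adjusted within its category and ranked
#' ascending by p-value (ties broken lexicographically by term). Drug
#' tables are reported as a direct lookup of the drugs known to modulate
#' query targets, without a test.
#'
#' @param query A [batch_query()], or a character vector resolved against
#'   the first table's universe.
#' @param tables A single [annotation_table()] or a list of them.
#' @param adjust Apply BH adjustment within category (default `TRUE`;
#'   switch off to rank by raw p-values only, in which case `adjusted_p`
#'   repeats `p_value`).
#' @return A `batch_report` object whose `results` tibble has one row per
#'   (category, term): `category`, `term_id`, `k` (overlap), `K` (set
#'   size), `n` (query size), `N` (universe size), `p_value`, `adjusted_p`,
#'   plus a `drugs` tibble of direct lookups.
#' @examples
#' cfg <- fixture_config(n_targets = 30, n_diseases = 5, seed = 7,
#'                       planted_term = list(term = "PW_PLANT", n_members = 6))
#' anno <- simulate_annotations(cfg)
#' report <- batch_search(anno$sets[["PW_PLANT"]], anno)
#' tidy(report)
#' @export
batch_search <- function(query, tables, adjust = TRUE) {
  if (inherits(tables, "annotation_table")) tables <- list(tables)
  stopifnot(all(vapply(tables, inherits, TRUE, "annotation_table")))
  if (!inherits(query, "batch_query")) {
    query <- batch_query(query, universe = tables[[1]]$universe)
  }
  if (length(query$resolved) == 0L) {
    stop("empty-query error: no submitted identifier resolved to the universe",
         call. = FALSE)
  }
  genes <- query$resolved
  test_one <- function(tab) {
    N <- length(tab$universe)
    n <- sum(genes %in% tab$universe)
    rows <- purrr::imap(tab$sets, function(members, term) {
      k <- length(intersect(genes, members))
      if (k < 1L) return(NULL)
      tibble::tibble(category = tab$category, term_id = term, k = k,
                     K = length(members), n = n, N = N,
                     p_value = hypergeom_tail(k, length(members), n, N))
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out)) {
      out$adjusted_p <- if (adjust) bh_adjust(out$p_value) else out$p_value
      out <- dplyr::arrange(out, .data$p_value, .data$term_id)
    }
    out
  }
  is_drug <- vapply(tables, function(t) t$category == "drug", TRUE)
  results <- dplyr::bind_rows(lapply(tables[!is_drug], test_one))
  drugs <- dplyr::bind_rows(lapply(tables[is_drug], function(tab) {
    rows <- purrr::imap(tab$sets, function(members, term) {
      hits <- intersect(genes, members)
      if (!length(hits)) return(NULL)
      tibble::tibble(drug_id = term, targets = list(sort(hits)),
                     n_targets = length(hits))
    })
    dplyr::bind_rows(rows)
  }))
  structure(list(query = query, results = results, drugs = drugs),
            class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf(
    "<batch_report> %d resolved / %d unresolved targets; %d terms tested across %d categories\n",
    length(x$query$resolved), length(x$query$unresolved), nrow(x$results),
    length(unique(x$results$category))))
  if (nrow(x$results)) print(utils::head(tibble::as_tibble(x$results), 10))
  invisible(x)
}
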