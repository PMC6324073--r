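#' Build the filtered target-disease bipartite graph
#'
#' Keeps exactly the association records supported by at least
#' `min_evidence` evidence strings and with overall score strictly greater
#' than `min_score` (the published noise filters: 3 and 0.1), then indexes
#' neighbor sets and degrees on both sides.
#'
#' @param associations Association tibble from [aggregate_associations()]
#'   (columns `target_id`, `disease_id`, `overall`, `n_evidence`).
#' @param min_evidence Minimum evidence count per edge (inclusive).
#' @param min_score Overall-score cutoff (strict).
#' @return A `bipartite_graph` object: the retained `edges` tibble, neighbor
#'   maps `target_neighbors` / `disease_neighbors`, degree vectors and the
#'   thresholds used.
#' @export
build_graph <- function(associations, min_evidence = 3, min_score = 0.1) {
  edges <- associations |>
    tibble::as_tibble() |>
    dplyr::select("target_id", "disease_id", "overall", "n_evidence") |>
    dplyr::filter(.data$n_evidence >= min_evidence,
                  .data$overall > min_score)
  tn <- split(edges$disease_id, edges$target_id)
  dn <- split(edges$target_id, edges$disease_id)
  structure(list(
    edges = edges,
    target_neighbors = tn,
    disease_neighbors = dn,
    target_degree = lengths(tn),
    disease_degree = lengths(dn),
    thresholds = c(min_evidence = min_evidence, min_score = min_score)
  ), class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf(
    "<bipartite_graph> %d edges, %d targets, %d diseases (>= %g evidence, score > %g)\n",
    nrow(x$edges), length(x$target_neighbors), length(x$disease_neighbors),
    x$thresholds[["min_evidence"]], x$thresholds[["min_score"]]))
  invisible(x)
}

graph_side <- function(graph, side = c("targets", "diseases")) {
  side <- match.arg(side)
  if (side == "targets") {
    list(sets = graph$target_neighbors, opp_degree = graph$disease_degree)
  } else {
    list(sets = graph$disease_neighbors, opp_degree = graph$target_degree)
  }
}

#' Relationship score between two targets (or two diseases)
#'
#' Ratio of shared neighbors to the total neighbors of both entities. In
#' `"unweighted"` mode this is the Jaccard index of the two neighbor sets.
#' The default `"weighted"` mode weights each neighbor by the inverse of its
#' graph degree, so a shared rare disease pulls two targets closer than a
#' shared data-rich disease (and symmetrically for diseases sharing
#' specific targets). The `denominator` flag switches the total from the
#' union (default; identical sets then score exactly 1) to the sum of both
#' set sizes.
#'
#' @param graph A [build_graph()] result.
#' @param a,b Entity identifiers on the chosen side.
#' @param side `"targets"` (score by shared diseases) or `"diseases"`
#'   (score by shared targets).
#' @param weighting `"weighted"` (inverse-degree) or `"unweighted"`.
#' @param denominator `"union"` or `"sum"`.
#' @param top Reporting cap for the ranked shared-neighbor list (default 20).
#' @return One-row tibble: `entity_a`, `entity_b`, `score` in `[0, 1]` and a
#'   `shared` list-column of shared neighbors ranked by weight (rarest
#'   first), truncated at `top`.
#' @export
relationship_score <- function(graph, a, b, side = c("targets", "diseases"),
                               weighting = c("weighted", "unweighted"),
                               denominator = c("union", "sum"), top = 20) {
  side <- match.arg(side)
  weighting <- match.arg(weighting)
  denominator <- match.arg(denominator)
  gs <- graph_side(graph, side)
  for (id in c(a, b)) {
    if (!id %in% names(gs$sets)) {
      stop(sprintf("lookup error: '%s' is not a %s vertex of the graph",
                   id, sub("s$", "", side)), call. = FALSE)
    }
  }
  na <- gs$sets[[a]]
  nb <- gs$sets[[b]]
  shared <- intersect(na, nb)
  uni <- union(na, nb)
  w <- function(ids) {
    if (weighting == "weighted") 1 / gs$opp_degree[ids] else
      setNames(rep(1, length(ids)), ids)
  }
  num <- sum(w(shared))
  den <- if (denominator == "union") sum(w(uni)) else sum(w(na)) + sum(w(nb))
  score <- if (den == 0) 0 else num / den
  ws <- w(shared)
  ord <- if (length(ws)) order(-ws, names(ws)) else integer(0)
  tibble::tibble(entity_a = a, entity_b = b, score = score,
                 shared = list(utils::head(names(ws)[ord], top)))
}

#' MinHash LSH settings
#'
#' @param num_hashes Signature length (default 128).
#' @param bands Number of LSH bands (default 32); `bands * rows_per_band`
#'   must equal `num_hashes`.
#' @param rows_per_band Signature rows per band (default 4).
#' @param seed Integer seed for the hash family; recorded so candidate sets
#'   are reproducible.
#' @param candidate_threshold Jaccard lower bound below which pairs are
#'   skipped via the size-ratio heuristic
#'   `J(a, b) <= min(|A|, |B|) / max(|A|, |B|)` (unweighted mode only).
#'   Default 0: nothing is skipped.
#' @return An `lsh_config` list.
#' @export
lsh_config <- function(num_hashes = 128L, bands = 32L,
                       rows_per_band = num_hashes %/% bands, seed = 1L,
                       candidate_threshold = 0) {
  if (bands * rows_per_band != num_hashes) {
    stop("domain error: bands * rows_per_band must equal num_hashes",
         call. = FALSE)
  }
  structure(list(num_hashes = as.integer(num_hashes),
                 bands = as.integer(bands),
                 rows_per_band = as.integer(rows_per_band),
                 seed = as.integer(seed),
                 candidate_threshold = candidate_threshold),
            class = "lsh_config")
}

# prime modulus small enough that a * x stays exactly representable
.minhash_prime <- 1048573

#' MinHash signatures of a list of sets
#'
#' Universal hashing `(a * x + b) mod p` over the item universe; signature
#' row `i` of a set is the minimum of hash `i` over its members. The
#' per-hash collision probability of two sets equals their Jaccard index.
#'
#' @param sets Named list of character vectors.
#' @param config An [lsh_config()]; the seed determines the hash family.
#' @return `num_hashes` x `length(sets)` numeric matrix with sets as named
#'   columns.
#' @export
minhash_signatures <- function(sets, config = lsh_config()) {
  universe <- unique(unlist(sets, use.names = FALSE))
  u <- length(universe)
  if (u >= .minhash_prime) {
    stop("domain error: item universe exceeds the MinHash modulus",
         call. = FALSE)
  }
  p <- .minhash_prime
  ab <- withr::with_seed(config$seed, {
    list(a = sample.int(p - 1, config$num_hashes, replace = TRUE),
         b = sample.int(p, config$num_hashes, replace = TRUE) - 1)
  })
  idx <- lapply(sets, function(s) match(s, universe))
  sig <- matrix(NA_real_, nrow = config$num_hashes, ncol = length(sets),
                dimnames = list(NULL, names(sets)))
  x <- seq_len(u)
  for (i in seq_len(config$num_hashes)) {
    hv <- (ab$a[i] * x + ab$b[i]) %% p
    sig[i, ] <- vapply(idx, function(ix) min(hv[ix]), numeric(1))
  }
  sig
}

#' LSH candidate pairs on one side of the graph
#'
#' Splits each entity's MinHash signature into bands and returns every pair
#' of entities sharing all rows of at least one band. Deterministic given
#' the config seed.
#'
#' @param graph A [build_graph()] result.
#' @param side `"targets"` or `"diseases"`.
#' @param config An [lsh_config()].
#' @return Tibble of candidate pairs `entity_a < entity_b`
#'   (lexicographically); empty when the side is empty.
#' @export
lsh_candidates <- function(graph, side = c("targets", "diseases"),
                           config = lsh_config()) {
  side <- match.arg(side)
  sets <- graph_side(graph, side)$sets
  empty <- tibble::tibble(entity_a = character(), entity_b = character())
  if (length(sets) < 2L) return(empty)
  sig <- minhash_signatures(sets, config)
  ids <- colnames(sig)
  pairs <- list()
  for (bd in seq_len(config$bands)) {
    rows <- ((bd - 1L) * config$rows_per_band + 1L):(bd * config$rows_per_band)
    keys <- apply(sig[rows, , drop = FALSE], 2, paste, collapse = "_")
    for (bucket in split(ids, keys)) {
      if (length(bucket) >= 2L) {
        cmb <- utils::combn(sort(bucket), 2)
        pairs[[length(pairs) + 1L]] <-
          tibble::tibble(entity_a = cmb[1, ], entity_b = cmb[2, ])
      }
    }
  }
  if (!length(pairs)) return(empty)
  dplyr::distinct(dplyr::bind_rows(pairs)) |>
    dplyr::arrange(.data$entity_a, .data$entity_b)
}

#' Rank the entities most similar to a target (or disease)
#'
#' Scores [relationship_score()] between `entity` and every candidate and
#' returns the top `k`. On graph sides of up to `exact_limit` entities every
#' other entity is scored exactly; larger sides are shortlisted with
#' [lsh_candidates()] first. In unweighted mode, pairs whose size-ratio
#' Jaccard bound falls below `config$candidate_threshold` are skipped before
#' scoring.
#'
#' @inheritParams relationship_score
#' @param entity Identifier of the query entity.
#' @param k Number of neighbors to return; fewer are returned when fewer
#'   candidates share anything (no padding).
#' @param config An [lsh_config()].
#' @param exact_limit Side size up to which all pairs are scored exactly.
#' @return A `similar_entities` tibble of up to `k` rows ranked by
#'   descending score, ties broken lexicographically by identifier.
#' @export
similar_entities <- function(graph, entity, side = c("targets", "diseases"),
                             k = 20, weighting = c("weighted", "unweighted"),
                             config = lsh_config(), exact_limit = 1000,
                             denominator = c("union", "sum")) {
  side <- match.arg(side)
  weighting <- match.arg(weighting)
  denominator <- match.arg(denominator)
  sets <- graph_side(graph, side)$sets
  if (!entity %in% names(sets)) {
    stop(sprintf("lookup error: '%s' is not a %s vertex of the graph",
                 entity, sub("s$", "", side)), call. = FALSE)
  }
  others <- setdiff(names(sets), entity)
  if (length(others) > exact_limit) {
    cand <- lsh_candidates(graph, side, config)
    others <- union(cand$entity_b[cand$entity_a == entity],
                    cand$entity_a[cand$entity_b == entity])
  }
  if (weighting == "unweighted" && config$candidate_threshold > 0) {
    sz <- lengths(sets)
    bound <- pmin(sz[entity], sz[others]) / pmax(sz[entity], sz[others])
    others <- others[bound >= config$candidate_threshold]
  }
  scored <- purrr::map(sort(others), function(b) {
    relationship_score(graph, entity, b, side = side, weighting = weighting,
                       denominator = denominator)
  })
  out <- dplyr::bind_rows(scored)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(entity_a = character(), entity_b = character(),
                          score = double(), shared = list())
  }
  out <- out |>
    dplyr::arrange(dplyr::desc(.data$score), .data$entity_b) |>
    utils::head(k)
  class(out) <- c("similar_entities", class(out))
  out
}
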