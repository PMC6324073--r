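#' Configuration for synthetic evidence corpora and annotation tables
#'
#' Describes a deterministic synthetic study: a universe of targets and
#' diseases, per-source background evidence rates, optional planted
#' target-disease associations with a requested overall score, and an
#' optional planted enriched annotation term. One integer seed fully
#' determines every generated file.
#'
#' @param n_targets,n_diseases Universe sizes.
#' @param seed Integer seed driving the generator's random stream.
#' @param sources Tibble with columns `data_source` and `rate` (expected
#'   number of background evidence records for that source). Default: seven
#'   representative sources at two expected records per target each.
#' @param planted_pairs Optional tibble with columns `target`, `disease`
#'   (identifiers, or 1-based indices into the universe) and `overall`, the
#'   requested aggregated overall association score in `[0, 1]`.
#' @param planted_evidence Evidence strings emitted per planted pair
#'   (default 3, enough to pass the similarity-graph evidence filter).
#' @param planted_term Optional list with `term` (identifier) and either
#'   `members` (target identifiers) or `n_members` (count; the first so-many
#'   targets are used) for the planted enriched annotation set.
#' @param n_terms,term_size Number of random background annotation terms and
#'   the inclusive range their sizes are drawn from.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_targets, n_diseases, seed,
                           sources = NULL, planted_pairs = NULL,
                           planted_evidence = 3L, planted_term = NULL,
                           n_terms = 10L, term_size = c(4L, 12L)) {
  stopifnot(n_targets >= 1, n_diseases >= 1)
  targets <- sprintf("ENSG%011d", seq_len(n_targets))
  diseases <- sprintf("EFO_%07d", seq_len(n_diseases))
  if (is.null(sources)) {
    sources <- tibble::tibble(
      data_source = c("gwas_catalog", "phewas_catalog", "genomics_england",
                      "eva", "cancer_gene_census", "chembl", "europepmc"),
      rate = 2 * n_targets
    )
  }
  if (!is.null(planted_pairs)) {
    planted_pairs <- tibble::as_tibble(planted_pairs)
    planted_pairs$target <- resolve_entity(planted_pairs$target, targets,
                                           "target")
    planted_pairs$disease <- resolve_entity(planted_pairs$disease, diseases,
                                            "disease")
    if (any(planted_pairs$overall < 0 | planted_pairs$overall > 1)) {
      stop("planting error: requested overall score outside [0, 1]",
           call. = FALSE)
    }
  }
  if (!is.null(planted_term)) {
    if (is.null(planted_term$members)) {
      k <- planted_term$n_members %||% 5L
      planted_term$members <- targets[seq_len(min(k, n_targets))]
    }
    if (!all(planted_term$members %in% targets)) {
      stop("config error: planted term members outside the target universe",
           call. = FALSE)
    }
  }
  structure(list(
    n_targets = n_targets, n_diseases = n_diseases, seed = as.integer(seed),
    targets = targets, diseases = diseases, sources = sources,
    planted_pairs = planted_pairs,
    planted_evidence = as.integer(planted_evidence),
    planted_term = planted_term, n_terms = as.integer(n_terms),
    term_size = as.integer(term_size)
  ), class = "fixture_config")
}

resolve_entity <- function(x, universe, what) {
  if (is.numeric(x)) {
    if (any(x < 1 | x > length(universe))) {
      stop(sprintf("planting error: %s index out of range", what),
           call. = FALSE)
    }
    return(universe[x])
  }
  if (!all(x %in% universe)) {
    stop(sprintf("planting error: planted %s not in the universe", what),
         call. = FALSE)
  }
  x
}

sample_payload <- function(rule) {
  switch(rule,
    pvalue = list(p_value = 10^runif(1, -30, 0)),
    phewas = list(p_value = 10^runif(1, -30, 0),
                  n_cases = sample.int(12000L, 1L)),
    panelapp = list(panel = sprintf("panel_%d", sample.int(200L, 1L))),
    cgc = list(tier = sample(1:2, 1L),
               poisson_fdr_disease = runif(1),
               poisson_fdr_pan = runif(1),
               n_mutated_samples = sample.int(50L, 1L),
               mutation_type = sample(c("missense", "nonsense", "fusion"),
                                      1L),
               fusion_only = runif(1) < 0.2),
    clinvar = list(clinical_significance =
                     sample(names(clinvar_default_map()), 1L)),
    list(precomputed_score = runif(1))
  )
}

#' Generate a synthetic evidence corpus
#'
#' Draws background evidence per source at its configured rate, with
#' payloads sampled inside each rule's valid domain (log-uniform p-values,
#' case counts up to 12000, uniform tiers, FDRs and sample counts). Each
#' planted pair additionally receives `planted_evidence` records from a
#' precomputed-score source, all carrying the requested overall score, so
#' its aggregated overall association score equals the request exactly
#' (normalized harmonic sums leave constant vectors unchanged). Background
#' records never land on planted pairs. Output is identical for identical
#' seeds, and every configured target appears at least once.
#'
#' @param config A [fixture_config()].
#' @return An unscored evidence tibble in [read_evidence()] shape.
#' @export
simulate_evidence <- function(config) {
  registry <- default_registry()
  planted_keys <- if (is.null(config$planted_pairs)) character(0) else
    paste(config$planted_pairs$target, config$planted_pairs$disease)
  withr::with_seed(config$seed, {
    rows <- list()
    for (s in seq_len(nrow(config$sources))) {
      src <- config$sources$data_source[s]
      rule <- registry_lookup(registry, src)$rule
      n_ev <- rpois(1, config$sources$rate[s])
      if (n_ev == 0L) next
      tg <- sample(config$targets, n_ev, replace = TRUE)
      ds <- sample(config$diseases, n_ev, replace = TRUE)
      # background evidence must not perturb planted pairs: redraw clashes
      while (any(clash <- paste(tg, ds) %in% planted_keys)) {
        tg[clash] <- sample(config$targets, sum(clash), replace = TRUE)
        ds[clash] <- sample(config$diseases, sum(clash), replace = TRUE)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        target_id = tg, disease_id = ds, data_source = src,
        payload = lapply(seq_len(n_ev), function(e) sample_payload(rule))
      )
    }
    ev <- dplyr::bind_rows(rows)
    # guarantee coverage: one genetic record for any target never drawn
    missing <- setdiff(config$targets, ev$target_id)
    for (tg in missing) {
      repeat {
        ds <- sample(config$diseases, 1L)
        if (!paste(tg, ds) %in% planted_keys) break
      }
      ev <- dplyr::bind_rows(ev, tibble::tibble(
        target_id = tg, disease_id = ds, data_source = "gwas_catalog",
        payload = list(sample_payload("pvalue"))
      ))
    }
    if (!is.null(config$planted_pairs)) {
      for (i in seq_len(nrow(config$planted_pairs))) {
        pp <- config$planted_pairs[i, ]
        ev <- dplyr::bind_rows(ev, tibble::tibble(
          target_id = rep(pp$target, config$planted_evidence),
          disease_id = rep(pp$disease, config$planted_evidence),
          data_source = "chembl",
          payload = rep(list(list(precomputed_score = pp$overall)),
                        config$planted_evidence)
        ))
      }
    }
    ev$data_type <- registry_lookup(registry, ev$data_source)$data_type
    ev$score <- NA_real_
    ev$line <- seq_len(nrow(ev))
    ev[, c("line", "target_id", "disease_id", "data_source", "data_type",
           "score", "payload")]
  })
}

#' Generate synthetic annotation tables with a planted enriched term
#'
#' Draws `n_terms` random gene sets over the configured target universe and
#' appends the planted enriched term with exactly its stated members.
#' Deterministic per seed (the annotation stream is offset from the
#' evidence stream so the two corpora are independent draws).
#'
#' @param config A [fixture_config()].
#' @param category Annotation category for the generated table.
#' @return An [annotation_table()].
#' @export
simulate_annotations <- function(config, category = "pathway") {
  withr::with_seed(config$seed + 10007L, {
    sets <- lapply(seq_len(config$n_terms), function(i) {
      size <- sample(seq(config$term_size[1],
                         min(config$term_size[2], config$n_targets)), 1L)
      sample(config$targets, size)
    })
    names(sets) <- sprintf("TERM_%03d", seq_len(config$n_terms))
    if (!is.null(config$planted_term)) {
      sets[[config$planted_term$term]] <- config$planted_term$members
    }
    annotation_table(sets, config$targets, category)
  })
}

#' Write a complete fixture set to a directory
#'
#' Dog-foods the package's own readers: evidence as JSON Lines and the
#' annotation table as a tab-separated `term_id, gene_id` file.
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev_path <- file.path(dir, "evidence.jsonl")
  an_path <- file.path(dir, "annotations.tsv")
  write_evidence(simulate_evidence(config), ev_path)
  anno <- simulate_annotations(config)
  tbl <- tibble::tibble(
    term_id = rep(names(anno$sets), lengths(anno$sets)),
    gene_id = unlist(anno$sets, use.names = FALSE)
  )
  utils::write.table(tbl, an_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(evidence = ev_path, annotations = an_path))
}
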