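#' P-value scale for genetic-association evidence
#'
#' Boundaries of the linear `-log10(p)` score map: `p_max` is the floor
#' (scores 0) and `p_min` the ceiling (scores 1). Defaults are the published
#' GWAS/PheWAS range, 0.05 and 1e-25.
#'
#' @param p_max Probability at or above which the score is 0.
#' @param p_min Probability at or below which the score is 1.
#' @return A `pvalue_scale` list.
#' @export
pvalue_scale <- function(p_max = 0.05, p_min = 1e-25) {
  if (!(is.numeric(p_min) && is.numeric(p_max) &&
        p_min > 0 && p_min < p_max && p_max <= 1)) {
    stop("domain error: need 0 < p_min < p_max <= 1", call. = FALSE)
  }
  structure(list(p_max = p_max, p_min = p_min), class = "pvalue_scale")
}

#' PheWAS scoring parameters
#'
#' @param scale A [pvalue_scale()].
#' @param max_cases Case count at which the case-count factor saturates
#'   (default 8800, the published maximum).
#' @return A `phewas_params` list.
#' @export
phewas_params <- function(scale = pvalue_scale(), max_cases = 8800) {
  if (!(is.numeric(max_cases) && max_cases > 0)) {
    stop("domain error: max_cases must be positive", call. = FALSE)
  }
  structure(list(scale = scale, max_cases = max_cases),
            class = "phewas_params")
}

#' Score a p-value on the linear -log10 scale
#'
#' Maps p-values to `[0, 1]` linearly in `-log10(p)` between the scale
#' boundaries, clipped: `p >= p_max` scores 0 and `p <= p_min` scores 1.
#' Monotone non-increasing in `p`.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @param scale A [pvalue_scale()].
#' @return Numeric vector of unit-interval scores.
#' @examples
#' score_pvalue_linear(c(0.05, 1e-25, 1e-13))
#' @export
score_pvalue_linear <- function(p, scale = pvalue_scale()) {
  if (!is.numeric(p) || any(p <= 0 | p > 1)) {
    stop("domain error: p must lie in (0, 1]", call. = FALSE)
  }
  lo <- -log10(scale$p_max)
  hi <- -log10(scale$p_min)
  pmin(pmax((-log10(p) - lo) / (hi - lo), 0), 1)
}

#' Score PheWAS evidence
#'
#' The p-value factor from [score_pvalue_linear()] multiplied by the
#' case-count factor `min(n_cases / max_cases, 1)`: monotone non-increasing
#' in `p`, non-decreasing in `n_cases`, always in `[0, 1]`.
#'
#' @param p P-values in `(0, 1]`.
#' @param n_cases Non-negative case counts.
#' @param params A [phewas_params()].
#' @return Numeric vector of unit-interval scores.
#' @examples
#' score_phewas(1e-25, 4400)  # 0.5: half the maximum case count
#' @export
score_phewas <- function(p, n_cases, params = phewas_params()) {
  if (!is.numeric(n_cases) || any(n_cases < 0)) {
    stop("domain error: n_cases must be non-negative", call. = FALSE)
  }
  pmin(n_cases / params$max_cases, 1) * score_pvalue_linear(p, params$scale)
}

#' Score a Genomics England PanelApp record
#'
#' Green genes from version-1+ panels whose disease maps to an ontology term
#' carry maximal evidence: the score is exactly 1.
#'
#' @param ev A one-row evidence tibble or a list with `data_source` and
#'   `disease_id`.
#' @param source Registry name of the PanelApp source.
#' @return The score 1.0.
#' @export
score_panelapp <- function(ev, source = "genomics_england") {
  if (!identical(as.character(ev$data_source), source)) {
    stop(sprintf("rule-mismatch error: data_source '%s' is not '%s'",
                 ev$data_source, source), call. = FALSE)
  }
  d <- ev$disease_id
  if (is.null(d) || is.na(d) || !nzchar(d)) {
    stop("validation error: disease_id is empty (unmapped disease)",
         call. = FALSE)
  }
  1.0
}

#' Score a tiered Cancer Gene Census record
#'
#' All Cancer Gene Census mutations start from a base association score of
#' 0.5, then:
#' * tier 1: each of the two Poisson recurrence tests significant at
#'   `FDR < fdr_threshold` adds 0.25;
#' * tier 2: the score stays 0.5 regardless of the tests;
#' * genes driving cancer only through fusions: non-fusion mutation types for
#'   tier-1 genes revert to 0.5 (fusions keep the tier-1 rules);
#' * a single mutated sample subtracts 0.25.
#'
#' The fusion-only override is applied after the test increments and before
#' the single-sample subtraction (`rule_order = "fusion_then_single"`), which
#' is the ordering that never inflates a score; the alternative ordering is
#' available for comparison.
#'
#' @param tier Integer 1 or 2.
#' @param poisson_fdr_disease,poisson_fdr_pan FDRs of the two Poisson tests
#'   (gene vs other genes in the disease; gene in this disease vs all
#'   diseases), in `[0, 1]`. Default 1 (not significant).
#' @param n_mutated_samples Number of mutated samples, at least 1.
#' @param mutation_type Mutation type string (e.g. `"missense"`, `"fusion"`).
#' @param fusion_only Is the gene known to drive cancer only through fusions?
#' @param fdr_threshold Significance cutoff for the Poisson tests
#'   (default 0.025).
#' @param rule_order `"fusion_then_single"` (default) or
#'   `"single_then_fusion"`.
#' @return Numeric vector of unit-interval scores.
#' @examples
#' score_cgc(tier = 1, poisson_fdr_disease = 0.01, poisson_fdr_pan = 0.01,
#'           n_mutated_samples = 10)  # 1.0
#' score_cgc(tier = 2, n_mutated_samples = 10)  # 0.5
#' @export
score_cgc <- function(tier, poisson_fdr_disease = 1, poisson_fdr_pan = 1,
                      n_mutated_samples = 2, mutation_type = "missense",
                      fusion_only = FALSE, fdr_threshold = 0.025,
                      rule_order = c("fusion_then_single",
                                     "single_then_fusion")) {
  rule_order <- match.arg(rule_order)
  n <- max(length(tier), length(poisson_fdr_disease), length(poisson_fdr_pan),
           length(n_mutated_samples), length(mutation_type),
           length(fusion_only))
  tier <- rep_len(tier, n)
  fdr1 <- rep_len(poisson_fdr_disease, n)
  fdr2 <- rep_len(poisson_fdr_pan, n)
  nms <- rep_len(n_mutated_samples, n)
  mt <- rep_len(mutation_type, n)
  fo <- rep_len(fusion_only, n)
  if (any(!tier %in% c(1, 2))) {
    stop("domain error: tier must be 1 or 2", call. = FALSE)
  }
  if (any(nms < 1)) {
    stop("domain error: n_mutated_samples must be at least 1", call. = FALSE)
  }
  if (any(fdr1 < 0 | fdr1 > 1 | fdr2 < 0 | fdr2 > 1)) {
    stop("domain error: Poisson FDR values must lie in [0, 1]", call. = FALSE)
  }
  score <- rep(0.5, n)
  t1 <- tier == 1
  score[t1] <- score[t1] + 0.25 * (fdr1[t1] < fdr_threshold) +
    0.25 * (fdr2[t1] < fdr_threshold)
  fus_override <- t1 & fo & mt != "fusion"
  single <- nms == 1
  if (rule_order == "fusion_then_single") {
    score[fus_override] <- 0.5
    score[single] <- score[single] - 0.25
  } else {
    score[single] <- score[single] - 0.25
    score[fus_override] <- 0.5
  }
  pmin(pmax(score, 0), 1)
}

#' Default ClinVar clinical-significance score map
#'
#' Configuration default, not a published table: `pathogenic` carries the
#' maximal score and the remaining imported terms (`protective`,
#' `association`, `risk factor`, `affects`, `drug response`) an intermediate
#' 0.5.
#'
#' @return Named numeric vector mapping term to unit-interval score.
#' @export
clinvar_default_map <- function() {
  c(pathogenic = 1.0, protective = 0.5, association = 0.5,
    `risk factor` = 0.5, affects = 0.5, `drug response` = 0.5)
}

#' Score ClinVar evidence by clinical-significance term
#'
#' @param clinical_significance Term(s) to score.
#' @param map Named numeric map of term to score; see
#'   [clinvar_default_map()].
#' @return Numeric vector of unit-interval scores. Terms absent from the map
#'   raise an unknown-term error rather than scoring 0.
#' @export
score_clinvar <- function(clinical_significance, map = clinvar_default_map()) {
  if (any(map < 0 | map > 1)) {
    stop("domain error: clinical-significance scores must lie in [0, 1]",
         call. = FALSE)
  }
  unknown <- setdiff(unique(clinical_significance), names(map))
  if (length(unknown)) {
    stop("unknown-term error: clinical significance term(s) not in map: ",
         paste(sQuote(unknown, q = FALSE), collapse = ", "), call. = FALSE)
  }
  unname(map[clinical_significance])
}

#' Scoring configuration
#'
#' Bundles the tunables of every per-source rule, optionally read from a
#' YAML file with blocks `pvalue_scale {p_max, p_min}`, `phewas {max_cases}`,
#' `cgc {fdr_threshold, rule_order}` and `clinvar_map {term: score}`.
#'
#' @param file Optional YAML file overriding the defaults.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(file = NULL) {
  cfg <- list(
    pvalue_scale = pvalue_scale(),
    phewas = phewas_params(),
    cgc = list(fdr_threshold = 0.025, rule_order = "fusion_then_single"),
    clinvar_map = clinvar_default_map()
  )
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    if (!is.null(y$pvalue_scale)) {
      cfg$pvalue_scale <- pvalue_scale(
        p_max = y$pvalue_scale$p_max %||% 0.05,
        p_min = y$pvalue_scale$p_min %||% 1e-25
      )
    }
    if (!is.null(y$phewas)) {
      cfg$phewas <- phewas_params(scale = cfg$pvalue_scale,
                                  max_cases = y$phewas$max_cases %||% 8800)
    }
    if (!is.null(y$cgc)) {
      cfg$cgc$fdr_threshold <- y$cgc$fdr_threshold %||% cfg$cgc$fdr_threshold
      cfg$cgc$rule_order <- y$cgc$rule_order %||% cfg$cgc$rule_order
    }
    if (!is.null(y$clinvar_map)) {
      cfg$clinvar_map <- unlist(y$clinvar_map)
    }
  }
  cfg$phewas$scale <- cfg$pvalue_scale
  structure(cfg, class = "scoring_config")
}

#' Score a table of evidence strings
#'
#' Dispatches every record to the rule its data source is registered with;
#' sources without an in-package rule (drugs, text mining, animal models,
#' expression, precomputed pathway analyses) take
#' `payload$precomputed_score` verbatim.
#'
#' @param evidence Evidence tibble from [read_evidence()] or
#'   [simulate_evidence()].
#' @param registry Data-source registry.
#' @param config A [scoring_config()].
#' @return The evidence tibble with the `score` column filled; every score
#'   lies in `[0, 1]`.
#' @examples
#' ev <- simulate_evidence(fixture_config(n_targets = 4, n_diseases = 3,
#'                                        seed = 1))
#' score_evidence(ev)
#' @export
score_evidence <- function(evidence, registry = default_registry(),
                           config = scoring_config()) {
  entries <- registry_lookup(registry, evidence$data_source)
  evidence$score <- purrr::map_dbl(seq_len(nrow(evidence)), function(i) {
    pl <- evidence$payload[[i]]
    rule <- entries$rule[i]
    check_payload(pl, rule, evidence$line[i] %||% NA_integer_)
    switch(rule,
      pvalue = score_pvalue_linear(pl$p_value, config$pvalue_scale),
      phewas = score_phewas(pl$p_value, pl$n_cases, config$phewas),
      panelapp = score_panelapp(evidence[i, ]),
      cgc = score_cgc(
        tier = pl$tier,
        poisson_fdr_disease = pl$poisson_fdr_disease %||% 1,
        poisson_fdr_pan = pl$poisson_fdr_pan %||% 1,
        n_mutated_samples = pl$n_mutated_samples,
        mutation_type = pl$mutation_type %||% "missense",
        fusion_only = isTRUE(pl$fusion_only),
        fdr_threshold = config$cgc$fdr_threshold,
        rule_order = config$cgc$rule_order
      ),
      clinvar = score_clinvar(pl$clinical_significance, config$clinvar_map),
      precomputed = {
        if (is.null(pl$precomputed_score)) {
          stop(sprintf(
            "unscorable-evidence error: source '%s' has no rule and no precomputed_score",
            evidence$data_source[i]), call. = FALSE)
        }
        pl$precomputed_score
      },
      stop(sprintf("unscorable-evidence error: no rule '%s' for source '%s'",
                   rule, evidence$data_source[i]), call. = FALSE)
    )
  })
  evidence
}
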