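#' The seven evidence data types
#'
#' Canonical snake_case names of the seven data types every evidence source
#' belongs to: genetic associations, somatic mutations, drugs, affected
#' pathways, RNA expression, animal models and text mining (literature).
#'
#' @return Character vector of length seven.
#' @export
data_types <- function() {
  c("genetic_association", "somatic_mutation", "known_drug",
    "affected_pathway", "rna_expression", "animal_model", "literature")
}

#' Data-source registry
#'
#' Maps each evidence data source to its data type and to the scoring rule
#' used for its records. Sources whose scores are computed upstream carry the
#' `"precomputed"` rule and must supply `payload$precomputed_score`.
#'
#' @param extra Optional tibble with columns `data_source`, `data_type`,
#'   `rule` appended to (or overriding, by source name) the defaults.
#' @return A tibble with columns `data_source`, `data_type`, `rule`.
#' @examples
#' default_registry()
#' @export
default_registry <- function(extra = NULL) {
  reg <- tibble::tribble(
    ~data_source,          ~data_type,             ~rule,
    "gwas_catalog",        "genetic_association",  "pvalue",
    "phewas_catalog",      "genetic_association",  "phewas",
    "genomics_england",    "genetic_association",  "panelapp",
    "eva",                 "genetic_association",  "clinvar",
    "cancer_gene_census",  "somatic_mutation",     "cgc",
    "eva_somatic",         "somatic_mutation",     "clinvar",
    "chembl",              "known_drug",           "precomputed",
    "slapenrich",          "affected_pathway",     "precomputed",
    "progeny",             "affected_pathway",     "precomputed",
    "reactome",            "affected_pathway",     "precomputed",
    "expression_atlas",    "rna_expression",       "precomputed",
    "phenodigm",           "animal_model",         "precomputed",
    "europepmc",           "literature",           "precomputed"
  )
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    stopifnot(all(c("data_source", "data_type", "rule") %in% names(extra)))
    reg <- dplyr::bind_rows(
      dplyr::filter(reg, !.data$data_source %in% extra$data_source),
      extra[, c("data_source", "data_type", "rule")]
    )
  }
  validate_registry(reg)
  reg
}

validate_registry <- function(registry) {
  if (anyDuplicated(registry$data_source)) {
    stop("registry error: duplicated data_source entries", call. = FALSE)
  }
  bad <- setdiff(unique(registry$data_type), data_types())
  if (length(bad)) {
    stop("registry error: unknown data_type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(registry)
}

registry_lookup <- function(registry, source) {
  i <- match(source, registry$data_source)
  if (anyNA(i)) {
    stop("registry error: unknown data_source(s): ",
         paste(unique(source[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  registry[i, ]
}

# payload fields a scoring rule cannot do without
required_payload_fields <- function(rule) {
  switch(rule,
    pvalue      = "p_value",
    phewas      = c("p_value", "n_cases"),
    panelapp    = character(0),
    cgc         = c("tier", "n_mutated_samples"),
    clinvar     = "clinical_significance",
    precomputed = "precomputed_score",
    character(0)
  )
}
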