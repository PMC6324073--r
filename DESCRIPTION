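Package: targetrank
Title: Target-Disease Association Scoring, Similarity Networks and Batch
    Enrichment for Drug Target Prioritisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Standalone implementation of the evidence-scoring and
    association framework used by large open target-validation platforms.
    Per-source evidence scoring rules (GWAS/PheWAS p-value scaling,
    Genomics England PanelApp, tiered Cancer Gene Census, ClinVar clinical
    significance) produce unit-interval evidence scores which are
    aggregated into data-source, data-type and overall target-disease
    association scores with a normalized harmonic sum.  A filtered
    bipartite target-disease graph supports Jaccard-style target (and
    disease) relationship scores with MinHash locality-sensitive hashing
    for candidate generation, and a batch module ranks annotation terms
    for a target list with hypergeometric enrichment, a Poisson-binomial
    pathway-alteration tail and Benjamini-Hochberg adjustment.  A
    deterministic synthetic-fixture generator plants associations and
    enriched terms for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
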