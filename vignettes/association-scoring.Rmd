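---
title: "Scoring target-disease associations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring target-disease associations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetrank)
library(dplyr)
```

targetrank reimplements, as a standalone toolkit, the evidence-integration
framework popularised by the Open Targets Platform for drug target
identification: heterogeneous evidence strings linking a target (a gene) to
a disease (an ontology term) are scored on the unit interval, aggregated
into association scores, organised into a similarity network, and analysed
in batch with enrichment statistics. This vignette explains the model, its
tunable parameters, the numerical choices made where the published
description leaves the design open, and what the synthetic fixtures do and
do not demonstrate.

## The four-level scoring model

Scoring happens at four levels. Each **evidence string** receives a score
$s \in [0,1]$ from a rule specific to its data source. Evidence scores are
aggregated per **data source**, source scores per **data type** (one of
seven: genetic associations, somatic mutations, drugs, affected pathways,
RNA expression, animal models, text mining), and the **overall association
score** aggregates the data-source scores. Every aggregation step uses the
same operator, the normalized harmonic sum: for scores sorted in descending
order $s_{(1)} \ge s_{(2)} \ge \dots$,

$$
HS(s) \;=\; \frac{\sum_{i=1}^{\min(n,\,c)} s_{(i)} / i^{\,e}}
                 {\sum_{i=1}^{\min(n,\,c)} 1 / i^{\,e}},
$$

with exponent $e = 2$ and cap $c = 100$ by default. The published
description defers the exact formula to supplementary material, so the
normalization is a design choice here: dividing by the same-length
truncated maximum makes singletons and constant vectors fixed points
($HS([x]) = x$, $HS([x,\dots,x]) = x$), keeps the result in $[0,1]$, and
preserves monotonicity in every element — the properties the test suite
pins down. The raw (unnormalized) sum, the exponent and the cap are all
configurable through `harmonic_config()`, as is whether the overall score
aggregates source scores (the default, matching the published wording) or
type scores.

The cap exists because text mining can contribute thousands of evidence
strings per pair; rank-$i$ terms are discounted by $1/i^2$, so terms beyond
rank 100 change the score by less than $10^{-4}$ anyway.

## Per-source scoring rules

**Linear p-value scale.** GWAS-style genetic evidence is scored linearly in
$-\log_{10} p$ between a floor $p_{\max} = 0.05$ (score 0) and a ceiling
$p_{\min} = 10^{-25}$ (score 1), clipped outside. The published account
gives both boundaries but defers the functional form to help documentation;
the linear map is the simplest monotone function honouring both printed
endpoints and is what `score_pvalue_linear()` implements.

**PheWAS.** PheWAS associations are additionally scaled by the number of
cases: the score is the product of the p-value factor and
$\min(n_{\text{cases}} / 8800,\, 1)$, where 8800 is the published maximum
case count of the PheWAS data. The product is chosen because both factors
are described as scalings; it keeps the score in $[0,1]$ and preserves both
monotonicities (non-increasing in $p$, non-decreasing in cases).

**PanelApp.** Diagnostic-grade ("Green") genes from Genomics England
PanelApp panels, with their disease mapped to an ontology term, carry the
maximum score of 1, regardless of the disease.

**Tiered Cancer Gene Census.** Somatic-mutation evidence starts from a base
score of 0.5. For tier-1 driver genes, each of the two Poisson recurrence
tests (gene vs other genes within the disease; gene in this disease vs all
diseases) significant at FDR < 0.025 adds 0.25. Tier-2 genes stay at 0.5
regardless of the tests. Genes known to drive cancer only through fusions
revert to 0.5 for every non-fusion mutation type (fusions keep the tier-1
increments). A single mutated sample subtracts 0.25. The published rules do
not specify the order of the fusion-only override and the single-sample
subtraction; `score_cgc()` applies the override first, which is the
ordering that can only lower a score, never inflate one, and exposes the
alternative via `rule_order` for comparison. The two Poisson FDRs arrive in
the evidence payload; recomputing them from raw mutation matrices is out of
scope.

**ClinVar clinical significance.** Clinical-significance terms map to
scores through a configurable table. The default assigns `pathogenic` 1.0
and the other imported terms (`protective`, `association`, `risk factor`,
`affects`, `drug response`) 0.5 each — an explicit configuration default,
since no published per-term values exist. Unknown terms raise an error
rather than silently scoring zero, so typos in upstream data surface.

Sources whose scoring happens upstream (ChEMBL drugs, text mining, animal
models, expression, precomputed pathway analyses) pass
`payload$precomputed_score` through verbatim.

## The similarity network

Associations form a bipartite graph with targets and diseases as vertices.
To reduce noise, `build_graph()` keeps only edges supported by at least 3
evidence strings whose overall score exceeds 0.1 (strictly) — both
published thresholds, both arguments.

The relationship score between two targets is the ratio of shared diseases
to the total diseases of both. Two published qualitative properties —
shared rare diseases matter more than shared data-rich ones, and
specifically-linked partners matter more than promiscuous ones — are
realised here as inverse-degree weights: disease $d$ contributes
$w_d = 1/\deg(d)$ to numerator and denominator, giving a weighted Jaccard
index. No published formula exists for this weighting, so the unweighted
Jaccard is available via `weighting = "unweighted"`. "Total for both
targets" is read as the union (so identical neighbour sets score exactly
1); the sum reading is available via `denominator = "sum"`. Shared diseases
are reported ranked rarest-first, capped at 20. Disease–disease similarity
is the same computation with the sides swapped.

For large graphs, candidate pairs come from MinHash LSH: 128 universal
hashes (modulus $2^{20} - 3$, a prime small enough that every product stays
exactly representable in doubles), banded as 32 bands of 4 rows, with the
hash-family seed recorded in the configuration. Two entities become
candidates when they agree on all rows of at least one band, which happens
with probability $1 - (1 - J^4)^{32}$ at Jaccard $J$ — essentially always
at $J \gtrsim 0.8$, essentially never at $J \approx 0$. A size-ratio bound
$J(a,b) \le \min(|A|,|B|) / \max(|A|,|B|)$ can additionally skip hopeless
pairs before scoring (unweighted mode only, where the bound is valid).
Graph sides of at most 1000 entities are scored exhaustively instead, so
small-graph results are exact by construction.

## Batch enrichment

`batch_search()` takes up to 200 target identifiers (the published batch
limit), collapses duplicates with a warning, resolves synonyms against a
local table, and tests every annotation term overlapping the query by at
least one gene with the upper-tail hypergeometric probability
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$ — over-representation
being the natural reading of ranking "by significance". Pathway terms use
the same statistic, with the specificity wording absorbed by conditioning
on the set size $K$. Within each category, p-values receive
Benjamini–Hochberg adjustment — an addition over the published description,
which mentions no multiplicity control; `adjust = FALSE` restores raw-p
ranking for fidelity. Drugs are reported as a direct lookup, not tested.

The Poisson-binomial tail, `poisson_binomial_tail()`, supports the
pathway-alteration statistic used for somatic-mutation pathway evidence: a
pathway counts as altered in a sample when at least one of its genes is
mutated (`pathway_alteration_prob()` gives $1 - \prod_g (1 - q_g)$), and
the number of altered samples is a sum of independent non-identical
Bernoulli trials. The tail is computed by exact dynamic-programming
convolution, $O(n^2)$, which is exact to machine precision and instant at
cohort scale.

## Synthetic fixtures: what they emulate, and what they do not

`fixture_config()` + `simulate_evidence()` / `simulate_annotations()`
generate deterministic corpora: background evidence per source at a
configurable expected rate (default: seven representative sources at two
expected records per target each, a density at which most target–disease
pairs have one or two supporting strings and a minority pass the
similarity-graph filters, qualitatively like a sparse release), with
payloads drawn inside each rule's valid domain — log-uniform p-values over
$[10^{-30}, 1]$, case counts up to 12000, uniform tiers, FDRs and sample
counts. A planted pair receives its evidence as three records from a
precomputed-score source, all equal to the requested overall score; because
normalized harmonic sums fix constant vectors, the aggregated overall
equals the request exactly. Planted enriched terms are inserted verbatim
into otherwise random annotation tables. One integer seed determines every
byte of output.

What passing the planted-recovery tests shows is that the pipeline is
internally consistent — scoring, aggregation, filtering, similarity and
enrichment compose without distorting known inputs. It does not show
calibration against real release data: real evidence is bursty and
correlated across sources, disease ontologies induce dependence between
terms, and real annotation sets overlap heavily. Production score
distributions will differ.

## Numerical and degenerate-input choices

* Empty score vectors aggregate to 0; empty graph sides yield empty
  candidate sets; an empty enrichment result is a valid empty tibble.
* Harmonic-sum ties in the descending sort cannot affect the result (the
  sum depends on values only), so no tie-break is needed beyond a stable
  sort.
* Probabilities are validated strictly: p-values in $(0,1]$, scores in
  $[0,1]$; violations raise domain errors rather than clamping.
* `hypergeom_tail()` delegates to `stats::phyper()`, which works in log
  space internally; the test suite checks it against exhaustive draw
  enumeration for all universes up to $N = 12$.
* The acceptance checks in the test suite run at deliberately small sizes —
  200-entity similarity graphs, 30-target enrichment universes, 15-target
  end-to-end pipelines, 100 seeded repetitions — chosen so the full suite
  completes in a few minutes while leaving the statistical claims (≥ 95/100
  and ≥ 99/100 recovery rates) sharp.

## Known limitations

* No ontology propagation: associations are not expanded to ancestor
  disease terms, and GO/Reactome hierarchies are not rolled up.
* Identifier handling is syntactic (prefix conventions behind a strictness
  flag, local synonym tables); nothing resolves against live services.
* The production platform's harmonic-sum normalization constant and any
  per-source weights live in its supplementary material and may differ from
  the defaults chosen here; all are configurable.
* The inverse-degree weighting is this package's concrete realisation of
  the published qualitative properties, not a published formula.
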