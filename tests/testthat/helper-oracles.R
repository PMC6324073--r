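# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's implementation paths.

# harmonic sum by direct formula evaluation
oracle_harmonic <- function(scores, exponent = 2, cap = 100,
                            normalize = TRUE) {
  if (length(scores) == 0) return(0)
  s <- sort(scores, decreasing = TRUE)
  m <- min(length(s), cap)
  total <- 0
  denom <- 0
  for (i in seq_len(m)) {
    total <- total + s[i] / i^exponent
    denom <- denom + 1 / i^exponent
  }
  if (normalize) total / denom else total
}

# literal rule-by-rule interpreter of the tiered Cancer Gene Census scoring
oracle_cgc <- function(tier, fdr1, fdr2, n_samples, mutation_type,
                       fusion_only, fdr_threshold = 0.025) {
  score <- 0.5
  if (tier == 1) {
    if (fdr1 < fdr_threshold) score <- score + 0.25
    if (fdr2 < fdr_threshold) score <- score + 0.25
  } else {
    score <- 0.5
  }
  if (tier == 1 && fusion_only && mutation_type != "fusion") score <- 0.5
  if (n_samples == 1) score <- score - 0.25
  min(max(score, 0), 1)
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws:
# the annotation set is taken to be genes 1..K of a universe 1..N
oracle_hypergeom <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Poisson-binomial upper tail by enumeration of all 2^n outcomes
oracle_poisson_binomial <- function(probs, k) {
  n <- length(probs)
  if (n == 0) return(as.numeric(k <= 0))
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) >= k) {
      total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
    }
  }
  total
}

# Benjamini-Hochberg step-up by the reference formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact Jaccard index of two character sets
oracle_jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) 0 else length(intersect(a, b)) / u
}

# evidence JSON line constructor for reader tests
ev_line <- function(target = "ENSG00000000001", disease = "EFO_0000001",
                    source = "chembl", payload = list(precomputed_score = 0.7),
                    score = NULL, extra = NULL) {
  rec <- list(target_id = target, disease_id = disease, data_source = source,
              payload = payload)
  if (!is.null(score)) rec$score <- score
  if (!is.null(extra)) rec <- c(rec, extra)
  as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
}
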