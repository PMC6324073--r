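fake_assoc <- function(edges) {
  # edges: tibble(target_id, disease_id, overall, n_evidence)
  out <- tibble::as_tibble(edges)
  out$source_scores <- rep(list(tibble::tibble()), nrow(out))
  out$type_scores <- rep(list(tibble::tibble()), nrow(out))
  out
}

star_graph <- function(pairs) {
  # pairs: named list target -> character vector of diseases
  edges <- tibble::tibble(
    target_id = rep(names(pairs), lengths(pairs)),
    disease_id = unlist(pairs, use.names = FALSE),
    overall = 0.5, n_evidence = 5L
  )
  build_graph(fake_assoc(edges))
}

test_that("graph filters apply the published thresholds with correct strictness", {
  edges <- tibble::tibble(
    target_id = sprintf("T%d", 1:4), disease_id = sprintf("D%d", 1:4),
    overall = c(0.2, 0.9, 0.1, 0.10001),
    n_evidence = c(3L, 2L, 5L, 5L)
  )
  g <- build_graph(fake_assoc(edges))
  kept <- g$edges
  expect_true("T1" %in% kept$target_id)      # 3 evidence, 0.2: boundary kept
  expect_false("T2" %in% kept$target_id)     # 2 evidence fails the count
  expect_false("T3" %in% kept$target_id)     # score 0.1 exactly: strict drop
  expect_true("T4" %in% kept$target_id)      # just above the cutoff
  expect_equal(unname(g$target_degree[c("T1", "T4")]), c(1L, 1L))
  expect_equal(glance(g)$n_edges, 2L)
})

test_that("relationship score matches set arithmetic in both modes", {
  g <- star_graph(list(A = c("d1", "d2", "d3"), B = c("d2", "d3", "d4")))
  expect_equal(relationship_score(g, "A", "B",
                                  weighting = "unweighted")$score, 0.5)
  # identical and disjoint neighbor sets
  g2 <- star_graph(list(A = c("d1", "d2"), B = c("d1", "d2"),
                        C = c("d3", "d4")))
  expect_equal(relationship_score(g2, "A", "B")$score, 1)
  expect_equal(relationship_score(g2, "A", "B",
                                  weighting = "unweighted")$score, 1)
  expect_equal(relationship_score(g2, "A", "C")$score, 0)
  expect_error(relationship_score(g2, "A", "nope"), "lookup error")
  # sum denominator counts both sides separately
  expect_equal(relationship_score(g2, "A", "B", weighting = "unweighted",
                                  denominator = "sum")$score, 0.5)
})

test_that("inverse-degree weighting makes shared rare diseases count more", {
  # degree(d2) = 1, degree(d3) = 10 via extra targets
  extra <- setNames(lapply(1:9, function(i) "d3"), sprintf("X%d", 1:9))
  g <- star_graph(c(list(A = c("d1", "d2", "d3"), B = c("d2", "d3", "d4")),
                    extra))
  rs <- relationship_score(g, "A", "B")
  # realized degrees: d1 1, d2 2 (A and B), d3 11, d4 1; the score is the
  # inverse-degree weighted Jaccard over those degrees
  expect_equal(rs$score, (1 / 2 + 1 / 11) / (1 + 1 / 2 + 1 / 11 + 1))
  # shared list ranks the rare disease first
  expect_equal(rs$shared[[1]], c("d2", "d3"))
  # symmetry
  expect_equal(relationship_score(g, "B", "A")$score, rs$score)

  # swapping a shared data-rich disease for a shared rare one raises the score
  g_rich <- star_graph(c(list(A = c("d1", "d3"), B = c("d3", "d4")), extra))
  g_rare <- star_graph(c(list(A = c("d1", "d2"), B = c("d2", "d4")), extra))
  expect_gt(relationship_score(g_rare, "A", "B")$score,
            relationship_score(g_rich, "A", "B")$score)
})

test_that("relationship score is 1 exactly when neighbor sets coincide", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      na <- sample(sprintf("d%d", 1:12), sample(2:8, 1))
      nb <- sample(sprintf("d%d", 1:12), sample(2:8, 1))
      g <- star_graph(list(A = na, B = nb))
      for (mode in c("weighted", "unweighted")) {
        s <- relationship_score(g, "A", "B", weighting = mode)$score
        expect_true(dplyr::between(s, 0, 1))
        expect_equal(s == 1, setequal(na, nb))
        expect_equal(relationship_score(g, "B", "A", weighting = mode)$score,
                     s)
      }
    }
  })
})

test_that("MinHash collision rate estimates Jaccard within 3 standard errors", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      na <- sample(sprintf("d%03d", 1:60), 30)
      nb <- sample(sprintf("d%03d", 1:60), 30)
      jac <- oracle_jaccard(na, nb)
      cfg <- lsh_config(seed = rep)
      sig <- minhash_signatures(list(a = na, b = nb), cfg)
      est <- mean(sig[, "a"] == sig[, "b"])
      se <- sqrt(jac * (1 - jac) / cfg$num_hashes)
      expect_lt(abs(est - jac), max(3 * se, 1e-9))
    }
  })
})

test_that("identical neighbor sets are always LSH candidates; disjoint ones almost never", {
  g <- star_graph(list(A = c("d1", "d2", "d3"), B = c("d1", "d2", "d3"),
                       C = c("d4", "d5", "d6")))
  hits_ab <- hits_ac <- 0
  for (seed in 1:100) {
    cand <- lsh_candidates(g, config = lsh_config(seed = seed))
    key <- paste(cand$entity_a, cand$entity_b)
    if ("A B" %in% key) hits_ab <- hits_ab + 1
    if ("A C" %in% key) hits_ac <- hits_ac + 1
  }
  expect_equal(hits_ab, 100)   # identical signatures always co-bucket
  expect_lte(hits_ac, 5)       # banding probability ~0 at J = 0
})

test_that("empty or singleton graph sides yield empty candidate sets", {
  g <- star_graph(list(A = c("d1", "d2")))
  expect_equal(nrow(lsh_candidates(g)), 0L)
  empty <- build_graph(fake_assoc(tibble::tibble(
    target_id = character(), disease_id = character(),
    overall = double(), n_evidence = integer())))
  expect_equal(nrow(lsh_candidates(empty)), 0L)
})

test_that("similar_entities matches the exact all-pairs ranking on small graphs", {
  cfg <- fixture_config(n_targets = 25, n_diseases = 15, seed = 41)
  g <- build_graph(aggregate_associations(
    score_evidence(simulate_evidence(cfg))))
  sets <- g$target_neighbors
  a <- names(sets)[1]
  got <- similar_entities(g, a, k = 10, weighting = "unweighted")
  exact <- sort(vapply(setdiff(names(sets), a), function(b) {
    oracle_jaccard(sets[[a]], sets[[b]])
  }, numeric(1)), decreasing = TRUE)
  expect_equal(got$score, unname(exact[seq_len(nrow(got))]))
  # unique sharer is the forced top hit
  g2 <- star_graph(list(A = c("d1", "d2"), B = c("d2", "d3"),
                        C = c("d4", "d5")))
  top <- similar_entities(g2, "A", k = 5)
  expect_equal(top$entity_b[1], "B")
  expect_equal(sum(top$score > 0), 1L)
  # k larger than the candidate count: no padding
  expect_lte(nrow(similar_entities(g2, "A", k = 50)), 2L)
  expect_error(similar_entities(g2, "ZZ"), "lookup error")
})

test_that("disease-side similarity reuses the same machinery with sides swapped", {
  g <- star_graph(list(A = c("d1", "d2"), B = c("d1", "d2"), C = "d1"))
  rs <- relationship_score(g, "d1", "d2", side = "diseases",
                           weighting = "unweighted")
  expect_equal(rs$score, 2 / 3)  # targets {A,B,C} vs {A,B}
  sim <- similar_entities(g, "d1", side = "diseases", k = 3)
  expect_equal(sim$entity_b[1], "d2")
})
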