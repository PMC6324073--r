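test_that("p-value scale maps its printed boundaries to 0 and 1", {
  expect_equal(score_pvalue_linear(0.05), 0)
  expect_equal(score_pvalue_linear(1e-25), 1)
  # log-midpoint of the scale scores one half
  mid <- 10^(-(-log10(0.05) + 25) / 2)
  expect_equal(score_pvalue_linear(mid), 0.5)
  # clipping outside the boundaries
  expect_equal(score_pvalue_linear(0.5), 0)
  expect_equal(score_pvalue_linear(1e-30), 1)
  expect_error(score_pvalue_linear(0), "domain error")
  expect_error(score_pvalue_linear(1.5), "domain error")
  expect_error(pvalue_scale(p_max = 1e-30, p_min = 0.05), "domain error")
})

test_that("PheWAS score is the product of case-count and p-value factors", {
  expect_equal(score_phewas(0.05, 8800), 0)
  expect_equal(score_phewas(1e-25, 8800), 1)
  expect_equal(score_phewas(1e-25, 4400), 0.5)
  expect_equal(score_phewas(1e-25, 17600), 1)  # case factor saturates
  expect_error(score_phewas(1e-5, -1), "domain error")
})

test_that("PheWAS score is monotone in both arguments and bounded", {
  withr::with_seed(42, {
    p <- sort(10^runif(50, -30, 0))
    s <- score_phewas(p, 5000)
    expect_true(all(diff(s) <= 1e-12))  # non-increasing in p
    ncase <- sort(sample.int(12000, 50))
    s2 <- score_phewas(1e-10, ncase)
    expect_true(all(diff(s2) >= -1e-12))  # non-decreasing in cases
    expect_true(all(s >= 0 & s <= 1 & s2 >= 0 & s2 <= 1))
  })
})

test_that("PanelApp Green-gene records always score exactly 1", {
  ev1 <- list(data_source = "genomics_england", disease_id = "EFO_0000001")
  ev2 <- list(data_source = "genomics_england", disease_id = "Orphanet_1")
  expect_identical(score_panelapp(ev1), 1.0)
  expect_identical(score_panelapp(ev2), 1.0)
  expect_error(score_panelapp(list(data_source = "phewas_catalog",
                                   disease_id = "EFO_1")),
               "rule-mismatch")
  expect_error(score_panelapp(list(data_source = "genomics_england",
                                   disease_id = "")),
               "unmapped")
})

test_that("CGC rule reproduces the printed modifier arithmetic", {
  # tier 2 is pinned at the 0.5 base whatever the Poisson tests say
  expect_equal(score_cgc(tier = 2, 0.5, 0.5, n_mutated_samples = 10), 0.5)
  expect_equal(score_cgc(tier = 2, 0.001, 0.001, n_mutated_samples = 10), 0.5)
  # tier 1: +0.25 per significant Poisson test at FDR < 0.025
  expect_equal(score_cgc(tier = 1, 0.01, 0.01, n_mutated_samples = 10), 1.0)
  expect_equal(score_cgc(tier = 1, 0.01, 0.5, n_mutated_samples = 10), 0.75)
  expect_equal(score_cgc(tier = 1, 0.5, 0.5, n_mutated_samples = 10), 0.5)
  # single mutated sample subtracts 0.25
  expect_equal(score_cgc(tier = 1, 0.5, 0.5, n_mutated_samples = 1), 0.25)
  # fusion-only genes: non-fusion mutation types revert to 0.5
  expect_equal(score_cgc(tier = 1, 0.001, 0.001, n_mutated_samples = 10,
                         mutation_type = "missense", fusion_only = TRUE),
               0.5)
  # ... while fusions keep the tier-1 increments
  expect_equal(score_cgc(tier = 1, 0.001, 0.001, n_mutated_samples = 10,
                         mutation_type = "fusion", fusion_only = TRUE),
               1.0)
  # threshold is strict: FDR exactly at the cutoff is not significant
  expect_equal(score_cgc(tier = 1, 0.025, 0.025, n_mutated_samples = 10), 0.5)
  expect_error(score_cgc(tier = 3, n_mutated_samples = 2), "domain error")
  expect_error(score_cgc(tier = 1, n_mutated_samples = 0), "domain error")
})

test_that("CGC scores match a brute-force rule interpreter over the full lattice", {
  grid <- expand.grid(tier = c(1, 2), fdr1 = c(0.001, 0.025, 0.9),
                      fdr2 = c(0.001, 0.025, 0.9), n_samples = c(1, 2, 10),
                      mutation_type = c("missense", "fusion"),
                      fusion_only = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  got <- with(grid, score_cgc(tier, fdr1, fdr2, n_samples, mutation_type,
                              fusion_only))
  want <- vapply(seq_len(nrow(grid)), function(i) {
    with(grid[i, ], oracle_cgc(tier, fdr1, fdr2, n_samples, mutation_type,
                               fusion_only))
  }, numeric(1))
  expect_equal(got, want)
  multi <- grid$n_samples > 1
  expect_true(all(got[multi] %in% c(0.25, 0.5, 0.75, 1.0)))
  expect_true(all(got[!multi] %in% c(0.0, 0.25, 0.5, 0.75)))
})

test_that("ClinVar clinical-significance lookup is a strict configurable map", {
  map <- clinvar_default_map()
  expect_setequal(names(map), c("pathogenic", "protective", "association",
                                "risk factor", "affects", "drug response"))
  expect_equal(score_clinvar("pathogenic"), unname(map["pathogenic"]))
  expect_equal(score_clinvar("protective", map = c(protective = 0.4)), 0.4)
  expect_error(score_clinvar("benign"), "unknown-term")
})

test_that("score_evidence dispatches by source and passes precomputed scores through", {
  lines <- c(
    ev_line(source = "genomics_england", payload = list()),
    ev_line(source = "chembl", payload = list(precomputed_score = 0.7)),
    ev_line(source = "phewas_catalog",
            payload = list(p_value = 1e-25, n_cases = 4400)),
    ev_line(source = "eva",
            payload = list(clinical_significance = "pathogenic"))
  )
  scored <- score_evidence(read_evidence(lines))
  expect_equal(scored$score, c(1.0, 0.7, 0.5, 1.0))
  expect_error(
    score_evidence(read_evidence(ev_line(source = "europepmc",
                                         payload = list(mined = TRUE)))),
    "precomputed_score")
})

test_that("every scoring rule stays inside the unit interval on random payloads", {
  withr::with_seed(7, {
    for (rep in 1:200) {
      p <- 10^runif(1, -40, 0)
      expect_true(dplyr::between(score_pvalue_linear(p), 0, 1))
      expect_true(dplyr::between(
        score_phewas(p, sample.int(20000, 1)), 0, 1))
      expect_true(dplyr::between(
        score_cgc(sample(1:2, 1), runif(1), runif(1), sample.int(50, 1),
                  sample(c("missense", "fusion", "nonsense"), 1),
                  runif(1) < 0.5), 0, 1))
    }
  })
})

test_that("scoring configuration can be read from YAML", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "pvalue_scale:", "  p_max: 0.01", "  p_min: 1.0e-20",
    "phewas:", "  max_cases: 5000",
    "cgc:", "  fdr_threshold: 0.05",
    "clinvar_map:", "  pathogenic: 0.9", "  benign: 0.1"
  ), yml)
  cfg <- scoring_config(yml)
  expect_equal(cfg$pvalue_scale$p_max, 0.01)
  expect_equal(cfg$phewas$max_cases, 5000)
  expect_equal(cfg$phewas$scale$p_min, 1e-20)
  expect_equal(cfg$cgc$fdr_threshold, 0.05)
  expect_equal(unname(cfg$clinvar_map["benign"]), 0.1)
  ev <- read_evidence(ev_line(source = "phewas_catalog",
                              payload = list(p_value = 1e-20, n_cases = 2500)))
  expect_equal(score_evidence(ev, config = cfg)$score, 0.5)
})
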