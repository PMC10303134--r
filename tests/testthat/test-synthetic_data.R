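test_that("generators are pure functions of spec and seed", {
  spec <- simulation_spec(n_individuals = 300,
                          variant_mafs = c(0.01, 0.1, 0.3), seed = 42)
  m <- pam_gene_model()
  expect_identical(simulate_positions(10, spec, m),
                   simulate_positions(10, spec, m))
  g1 <- simulate_genotypes(spec)
  g2 <- simulate_genotypes(spec)
  expect_identical(g1$dosages, g2$dosages)
  y1 <- simulate_phenotypes(g1, c(1, 2, 3), spec)
  expect_identical(y1, simulate_phenotypes(g2, c(1, 2, 3), spec))
  spec2 <- simulation_spec(n_individuals = 300,
                           variant_mafs = c(0.01, 0.1, 0.3), seed = 43)
  expect_false(identical(g1$dosages, simulate_genotypes(spec2)$dosages))
})

test_that("spec validation rejects boundary frequencies and prevalences", {
  expect_error(simulation_spec(variant_mafs = c(0, 0.1)), "\\(0, 0.5\\)")
  expect_error(simulation_spec(variant_mafs = 0.5), "\\(0, 0.5\\)")
  expect_error(simulation_spec(baseline_prevalence = 0), "\\(0, 1\\)")
})

test_that("distinct uniform positions exhaust the CDS at full occupancy", {
  m <- tiny_model()  # L = 30
  spec <- simulation_spec(seed = 5)
  expect_equal(simulate_positions(30, spec, m), 1:30)
  expect_error(simulate_positions(31, spec, m), "distinct positions")
})

test_that("clustered positions are detected by the clustering test", {
  m <- pam_gene_model()
  hits <- 0L
  for (i in 1:100) {
    spec <- simulation_spec(position_mode = "clustered", n_clusters = 1,
                            cluster_spread_bp = 10, seed = 1000 + i)
    pos <- simulate_positions(16, spec, m)
    p <- clustering_permutation_test(pos, m,
                                     perm_config(999, seed = i))$empirical_p
    if (p <= 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("uniform-null clustering p-values are approximately uniform", {
  m <- pam_gene_model()
  ps <- vapply(1:500, function(i) {
    spec <- simulation_spec(seed = 5000 + i)
    pos <- simulate_positions(16, spec, m)
    clustering_permutation_test(pos, m,
                                perm_config(999, seed = i))$empirical_p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("HWE genotypes recover their target allele frequencies", {
  spec <- simulation_spec(n_individuals = 10000, variant_mafs = 0.2, seed = 7)
  g <- simulate_genotypes(spec)
  se <- sqrt(0.2 * 0.8 / (2 * 10000))
  expect_lt(abs(mean(g$dosages) / 2 - 0.2), 3 * se)
  expect_true(all(g$dosages %in% 0:2))
})

test_that("null phenotypes are Bernoulli at the baseline prevalence", {
  spec <- simulation_spec(n_individuals = 50000, variant_mafs = c(0.1, 0.2),
                          baseline_prevalence = 0.1, seed = 9)
  g <- simulate_genotypes(spec)
  y <- simulate_phenotypes(g, c(10, 20), spec)  # beta_scale 0 under "null"
  expect_lt(abs(mean(y) - 0.1), 3 * sqrt(0.1 * 0.9 / 50000))
  # zero weights are distributionally identical to beta_scale 0
  spec_eff <- simulation_spec(n_individuals = 50000,
                              variant_mafs = c(0.1, 0.2),
                              effect_model = "weight_proportional",
                              beta_scale = 0.5, baseline_prevalence = 0.1,
                              seed = 9)
  expect_identical(simulate_phenotypes(g, c(0, 0), spec_eff), y)
})

test_that("weight-proportional effects raise carrier dosage among cases", {
  wins <- 0L
  for (i in 1:100) {
    spec <- simulation_spec(n_individuals = 1500,
                            variant_mafs = c(0.02, 0.05, 0.2),
                            effect_model = "weight_proportional",
                            beta_scale = 0.05, baseline_prevalence = 0.1,
                            seed = 200 + i)
    g <- simulate_genotypes(spec)
    w <- c(5, 10, 60)
    y <- simulate_phenotypes(g, w, spec)
    if (!any(y == 1) || !any(y == 0)) next
    top <- g$dosages[, which.max(w)]
    if (mean(top[y == 1]) > mean(top[y == 0])) wins <- wins + 1L
  }
  expect_gt(wins, 75L)
})

test_that("cohort-count generator is calibrated under no enrichment", {
  ps <- vapply(1:500, function(i) {
    cc <- simulate_cohort_counts(1, 0.05, 652, 150000, seed = 3000 + i)
    allele_count_test(cc$cohort, cc$controls)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("strong enrichment is detected with high probability", {
  ps <- vapply(1:200, function(i) {
    cc <- simulate_cohort_counts(50, 1e-4, 652, 150000, seed = 4000 + i)
    allele_count_test(cc$cohort, cc$controls)$p_value
  }, numeric(1))
  expect_lt(median(ps), 0.05)
})

test_that("impossible enrichment factors are rejected", {
  expect_error(simulate_cohort_counts(30, 0.05, 100, 100), "\\[0, 1\\]")
  expect_error(simulate_cohort_counts(1, 0, 100, 100), "\\(0, 1\\)")
})
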