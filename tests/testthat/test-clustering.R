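test_that("the clustering statistic matches closed forms and brute force", {
  expect_equal(geometric_mean_pairwise_distance(c(100, 200), 1000), 0.1)
  expect_equal(geometric_mean_pairwise_distance(c(10, 20, 30), 100),
               10 * 2^(1/3) / 100)
  # independent brute force: explicit double loop over all pairs
  pos <- pam_coding_positions()
  acc <- 0; np <- 0
  for (i in seq_along(pos)) for (j in seq_along(pos)) if (i < j) {
    acc <- acc + log(abs(pos[i] - pos[j])); np <- np + 1
  }
  expect_equal(np, 120)
  oracle <- exp(acc / np) / 2922
  expect_equal(geometric_mean_pairwise_distance(pos, 2922), oracle,
               tolerance = 1e-10)
  # frozen high-precision value for the same configuration
  expect_equal(geometric_mean_pairwise_distance(pos, 2922),
               0.216619218141545, tolerance = 1e-10)
})

test_that("degenerate position sets are rejected", {
  expect_error(geometric_mean_pairwise_distance(100, 1000), "at least 2")
  expect_error(geometric_mean_pairwise_distance(c(5, 5, 9), 100), "zero pairwise")
  expect_error(geometric_mean_pairwise_distance(c(5, 2000), 1000), "\\[1,")
})

test_that("the statistic is translation invariant and scales as 1/L", {
  base <- c(40, 90, 210, 355)
  s <- geometric_mean_pairwise_distance(base, 1000)
  expect_equal(geometric_mean_pairwise_distance(base + 500, 1000), s)
  expect_equal(geometric_mean_pairwise_distance(base, 2000), s / 2)
})

test_that("maximally spread pair gives p = 1 and the maximal statistic", {
  m <- tiny_model()  # L = 30
  res <- clustering_permutation_test(c(1, 30), m, perm_config(200, seed = 4))
  expect_equal(res$observed_statistic, 29 / 30)
  expect_equal(res$n_as_extreme, 200L)
  expect_equal(res$empirical_p, 1)
})

test_that("permutation p is reproducible and follows the add-one convention", {
  m <- pam_gene_model()
  pos <- c(100, 120, 150, 2800)
  a <- clustering_permutation_test(pos, m, perm_config(2000, seed = 7))
  b <- clustering_permutation_test(pos, m, perm_config(2000, seed = 7))
  expect_identical(a, b)
  expect_equal(a$empirical_p, (a$n_as_extreme + 1) / (a$n_permutations + 1))
  expect_gte(a$empirical_p, 1 / (a$n_permutations + 1))
  expect_error(
    clustering_permutation_test(c(5, 5, 9), m, perm_config(10, seed = 1)),
    "zero pairwise|distinct")
})

test_that("permutation p matches exhaustive enumeration at tiny size", {
  # all C(12,3) = 220 distinct position triples on a 12 bp CDS
  m <- gene_model("G", "T", 12L, 4L,
                  data.frame(name = "A", start_aa = 1L, end_aa = 4L))
  sets <- utils::combn(12, 3)
  all_stats <- apply(sets, 2, geometric_mean_pairwise_distance,
                     cds_length_bp = 12)
  expect_equal(ncol(sets), 220)
  pos <- c(2, 4, 7)
  obs <- geometric_mean_pairwise_distance(pos, 12)
  p_exact <- mean(all_stats <= obs)
  B <- 20000
  res <- clustering_permutation_test(pos, m, perm_config(B, seed = 21))
  mc_se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(res$empirical_p - p_exact), 3 * mc_se)
})

test_that("tighter clustering gives smaller empirical p at fixed n, L, seed", {
  m <- pam_gene_model()
  spreads <- list(c(1000, 1010, 1020, 1030),
                  c(1000, 1100, 1200, 1300),
                  c(200, 1000, 1800, 2600))
  ps <- vapply(spreads, function(pos)
    clustering_permutation_test(pos, m, perm_config(2000, seed = 5))$empirical_p,
    numeric(1))
  expect_true(all(diff(ps) >= 0))
})

test_that("a domain covering the whole CDS is never enriched", {
  m <- gene_model("G", "T", 12L, 4L,
                  data.frame(name = "ALL", start_aa = 1L, end_aa = 4L))
  res <- domain_count_permutation_test(c(2, 5, 11), m, perm_config(500, seed = 2))
  expect_equal(res$observed, 3)
  expect_equal(res$empirical_p, 1)
})

test_that("single-domain permutation p matches the binomial tail", {
  # one domain of fraction f under with-replacement uniform sampling
  m <- gene_model("G", "T", 300L, 100L,
                  data.frame(name = "D", start_aa = 1L, end_aa = 25L))
  f <- 75 / 300
  pos <- c(3, 10, 40, 50, 120, 200, 280, 299)  # k = 2 of n = 8 in the domain
  k <- sum(pos <= 75)
  B <- 20000
  res <- domain_count_permutation_test(
    pos, m, perm_config(B, seed = 31, sampling = "with_replacement"))
  p_binom <- pbinom(k - 1, length(pos), f, lower.tail = FALSE)
  mc_se <- sqrt(p_binom * (1 - p_binom) / B)
  expect_equal(res$observed[res$domain == "D"], k)
  expect_lt(abs(res$empirical_p[res$domain == "D"] - p_binom), 3 * mc_se)
})

test_that("domain counts for the PAM coding variants rank the N-terminus first", {
  res <- domain_count_permutation_test(pam_coding_positions(),
                                       pam_gene_model(),
                                       perm_config(5000, seed = 11))
  expect_equal(res$observed[match(c("PHMcc", "PALcc"), res$domain)], c(4, 7))
  expect_equal(res$domain[which.max(res$obs_over_exp)], "N-terminus")
})
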