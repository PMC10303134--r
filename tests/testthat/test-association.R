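test_that("intercept-only logistic null fits the case fraction", {
  y <- rep(c(0, 1), c(70, 30))
  null <- fit_null_binary(y)
  expect_equal(unique(round(null$fitted_means, 10)), 0.3)
  expect_lt(abs(sum(null$residuals)), 1e-8 * length(y))
  expect_true(null$converged)
  expect_error(fit_null_binary(rep(0, 50)), "both phenotype classes")
  expect_error(fit_null_binary(c(0, 1, 2)), "0/1")
})

test_that("logistic null matches a generic maximum-likelihood oracle", {
  set.seed(99)
  n <- 500
  X <- cbind(rnorm(n), rbinom(n, 1, 0.4))
  eta <- -1 + 0.8 * X[, 1] - 0.5 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  null <- fit_null_binary(y, X)
  # independent oracle: direct optimization of the bernoulli log-likelihood
  nll <- function(b) {
    lin <- cbind(1, X) %*% b
    -sum(y * lin - log1p(exp(lin)))
  }
  ora <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_lt(max(abs(unname(null$coefficients) - ora$par)), 1e-6)
})

test_that("Q collapses to the squared score for one variant and is invariant", {
  d <- null_dataset(200, c(0.1, 0.2, 0.3, 0.15, 0.4), seed = 8)
  null <- fit_null_binary(d$y)
  G <- d$g$dosages
  w <- c(5, 10, 20, 40, 60)
  # single variant, unit weight
  expect_equal(skat_q(G[, 1, drop = FALSE], 1, null),
               drop(crossprod(G[, 1], null$residuals))^2)
  expect_equal(skat_q(G, rep(0, 5), null), 0)
  # brute-force double-loop oracle
  q_oracle <- 0
  for (j in 1:5) {
    s <- 0
    for (i in 1:200) s <- s + null$residuals[i] * G[i, j]
    q_oracle <- q_oracle + w[j]^2 * s^2
  }
  expect_equal(skat_q(G, w, null), q_oracle, tolerance = 1e-10)
  # variant reordering leaves Q unchanged
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(skat_q(G[, perm], w[perm], null), skat_q(G, w, null))
  # permuting individuals together with phenotypes leaves Q unchanged
  ip <- sample(200)
  null2 <- fit_null_binary(d$y[ip])
  expect_equal(skat_q(G[ip, ], w, null2), skat_q(G, w, null),
               tolerance = 1e-8)
})

test_that("mean-dosage imputation preserves complete data and column means", {
  G <- matrix(c(0, 1, 2, 0, NA, 2, 1, 1, NA), nrow = 3)
  expect_identical(impute_mean_dosage(G[, 1, drop = FALSE]),
                   G[, 1, drop = FALSE])
  Gi <- impute_mean_dosage(G)
  expect_false(anyNA(Gi))
  expect_equal(colMeans(Gi), colMeans(G, na.rm = TRUE))
  Gfull <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3)
  expect_identical(impute_mean_dosage(Gfull), Gfull)
})

test_that("chi-square mixture tails match exact and Monte-Carlo oracles", {
  expect_equal(quadratic_form_pvalue(qchisq(0.95, 1), 1)$p, 0.05,
               tolerance = 1e-8)
  expect_equal(quadratic_form_pvalue(0, c(1, 2))$p, 1)
  # lambda {2,2} is 2 * chisq_2: closed form exp(-q/4)
  expect_equal(quadratic_form_pvalue(8, c(2, 2))$p, exp(-2),
               tolerance = 1e-8)
  # Monte-Carlo oracle for the mixture {2, 1, 0.5}
  set.seed(1234)
  draws <- 2 * rchisq(1e6, 1) + rchisq(1e6, 1) + 0.5 * rchisq(1e6, 1)
  mc <- mean(draws > 6)
  se <- sqrt(mc * (1 - mc) / 1e6)
  res <- quadratic_form_pvalue(6, c(2, 1, 0.5))
  expect_equal(res$method, "davies")
  expect_lt(abs(res$p - mc), 3 * se)
  # monotone non-increasing in q
  ps <- vapply(c(0.5, 1, 2, 4, 8, 16), function(q)
    quadratic_form_pvalue(q, c(2, 1, 0.5))$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(quadratic_form_pvalue(1, c(0, 0)), "all zero")
})

test_that("analytic and permutation SKAT p-values agree on a small instance", {
  d <- null_dataset(200, c(0.05, 0.1, 0.2, 0.3, 0.4), seed = 17)
  null <- fit_null_binary(d$y)
  res <- skat_test(d$g, c(5, 10, 20, 40, 60), null,
                   cfg = perm_config(10000, seed = 3))
  se <- sqrt(res$p_permutation * (1 - res$p_permutation) / 10000)
  expect_lt(abs(res$p - res$p_permutation), 3 * se)
})

test_that("common/rare partition is disjoint, exhaustive, and strict on MAF", {
  d <- null_dataset(600, c(0.0004, 0.0006, 0.01, 0.1, 0.3), seed = 23)
  null <- fit_null_binary(d$y)
  res <- common_rare_test(d$g, rep(1, 5), null, maf_cutoff_rare = 0.001,
                          cfg = perm_config(200, seed = 1))
  ids <- sort(c(res$rare_variant_ids, res$common_variant_ids))
  expect_equal(ids, sort(d$g$variant_ids))
  expect_length(intersect(res$rare_variant_ids, res$common_variant_ids), 0)
  expect_true(all(d$g$sample_mafs[match(res$rare_variant_ids,
                                        d$g$variant_ids)] < 0.001))
  expect_true(res$p_combined > 0 && res$p_combined <= 1)
  # explicit MAF override moves the boundary
  res2 <- common_rare_test(d$g, rep(1, 5), null, maf_cutoff_rare = 0.001,
                           cfg = perm_config(200, seed = 1),
                           maf = c(0.0001, 0.5, 0.5, 0.5, 0.5))
  expect_equal(res2$rare_variant_ids, d$g$variant_ids[1])
})

test_that("an empty partition degrades to the other partition's analytic p", {
  d <- null_dataset(400, c(0.1, 0.2, 0.3), seed = 29)
  null <- fit_null_binary(d$y)
  # all variants common at the default cutoff
  res <- common_rare_test(d$g, c(1, 2, 3), null,
                          cfg = perm_config(100, seed = 1))
  expect_length(res$rare_variant_ids, 0)
  st <- skat_test(d$g, c(1, 2, 3), null)
  expect_equal(res$p_combined, st$p)
  expect_equal(res$p_common, st$p)
  # degenerate grid on a single partition
  res1 <- common_rare_test(d$g, c(1, 2, 3), null, rho_grid = 1,
                           cfg = perm_config(100, seed = 1))
  expect_equal(res1$p_combined, res1$p_common)
})

test_that("Bonferroni thresholds reproduce the printed exome-wide cutoff", {
  expect_equal(bonferroni_threshold(0.05, 25000), 2e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})
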