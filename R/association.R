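#' Genotype matrix container
#'
#' Thin container for an individuals-by-variants dosage matrix (0/1/2 minor
#' allele counts; `NA` allowed). Sample minor-allele frequencies are the
#' folded column means / 2 after mean-dosage imputation.
#'
#' @param dosages Numeric matrix, individuals in rows, variants in columns.
#' @param variant_ids Optional variant identifiers (default: column names or
#'   `v1..vm`).
#' @param sample_ids Optional sample identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variant_ids = NULL, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (any(!is.na(dosages) & !(dosages %in% 0:2)))
    stop("dosages must be 0, 1, 2, or NA")
  if (any(colSums(!is.na(dosages)) == 0L))
    stop("all-missing variant column(s) present")
  variant_ids <- variant_ids %||% colnames(dosages) %||%
    paste0("v", seq_len(ncol(dosages)))
  sample_ids <- sample_ids %||% rownames(dosages) %||%
    paste0("s", seq_len(nrow(dosages)))
  dimnames(dosages) <- list(sample_ids, variant_ids)
  af <- colMeans(dosages, na.rm = TRUE) / 2
  structure(list(dosages = dosages,
                 variant_ids = variant_ids,
                 sample_ids = sample_ids,
                 sample_mafs = unname(pmin(af, 1 - af))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d variants (%.3g%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

as_dosage_matrix <- function(genotypes) {
  if (inherits(genotypes, "genotype_matrix")) genotypes$dosages
  else as.matrix(genotypes)
}

#' Impute missing dosages to the column mean
#'
#' Replaces each missing dosage with twice the sample allele frequency of
#' its variant (the column mean of the observed dosages), preserving column
#' means. A matrix without missing values is returned unchanged.
#'
#' @param dosages Numeric dosage matrix.
#' @return The imputed matrix.
#' @export
impute_mean_dosage <- function(dosages) {
  dosages <- as.matrix(dosages)
  miss <- is.na(dosages)
  if (!any(miss)) return(dosages)
  mu <- colMeans(dosages, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  dosages[idx] <- mu[idx[, 2L]]
  dosages
}

#' Fit the logistic null model for the score test
#'
#' Fits `phenotype ~ covariates` by logistic regression (iteratively
#' reweighted least squares, via [stats::glm()]) with an intercept; the
#' association tests are score tests computed from the residuals
#' `y - fitted`. Non-convergence or separation is flagged rather than
#' raised, and flagged models make [common_rare_test()] fall back to the
#' permutation p-value.
#'
#' @param phenotypes Binary 0/1 vector; both classes must be present.
#' @param covariates Optional numeric matrix/data.frame of covariates (no
#'   intercept column; one is added).
#' @return An object of class `rv_null_model` with elements `fitted_means`,
#'   `residuals`, `covariate_design`, `coefficients`, `converged`.
#' @export
fit_null_binary <- function(phenotypes, covariates = NULL) {
  y <- as.numeric(phenotypes)
  if (any(!y %in% c(0, 1))) stop("phenotypes must be 0/1")
  if (length(unique(y)) < 2L)
    stop("both phenotype classes must be present")
  n <- length(y)
  X <- if (is.null(covariates)) matrix(1, n, 1L,
                                       dimnames = list(NULL, "(Intercept)"))
       else cbind("(Intercept)" = 1, as.matrix(covariates))
  if (n <= ncol(X)) stop("more covariate columns than observations")
  converged <- TRUE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = binomial()),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) converged <- FALSE
  mu <- fit$fitted.values
  structure(list(fitted_means = mu,
                 residuals = y - mu,
                 covariate_design = X,
                 coefficients = fit$coefficients,
                 converged = converged),
            class = "rv_null_model")
}

#' @export
print.rv_null_model <- function(x, ...) {
  cat("Logistic null model:", length(x$residuals), "individuals,",
      ncol(x$covariate_design), "design column(s);",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Weighted variance-component score statistic
#'
#' `Q = sum_j w_j^2 (sum_i r_i g_ij)^2`, the SKAT-type quadratic form in the
#' null-model residuals `r` with per-variant weights `w`. Invariant to
#' variant ordering; all-zero weights give `Q = 0`.
#'
#' @param genotypes A [genotype_matrix()] or dosage matrix (missing values
#'   are mean-imputed).
#' @param weights Non-negative per-variant weight vector.
#' @param null An `rv_null_model` from [fit_null_binary()].
#' @return The non-negative scalar Q.
#' @export
skat_q <- function(genotypes, weights, null) {
  stopifnot(inherits(null, "rv_null_model"))
  G <- impute_mean_dosage(as_dosage_matrix(genotypes))
  if (ncol(G) != length(weights)) stop("one weight per variant is required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (nrow(G) != length(null$residuals))
    stop("genotype rows must match the null model")
  U <- drop(crossprod(G, null$residuals))
  sum((weights^2) * U^2)
}

# Null covariance of the score vector U = G'(y - mu) with covariates
# projected out: G'VG - G'VX (X'VX)^{-1} X'VG, V = diag(mu(1-mu)).
score_covariance <- function(G, null) {
  v <- null$fitted_means * (1 - null$fitted_means)
  X <- null$covariate_design
  GV <- G * v
  S <- crossprod(G, GV)
  XtVX <- crossprod(X, X * v)
  B <- crossprod(X, GV)                      # k x m
  S - crossprod(B, solve(XtVX, B))
}

# Eigenvalue spectrum of the weighted kernel W Sigma W, truncated at
# 1e-10 * max.
kernel_spectrum <- function(Sigma, weights) {
  A <- Sigma * tcrossprod(weights)
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-10 * max(ev, 0)]
  ev
}

imhof_integrand <- function(u, lambda, q) {
  theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
  logrho <- 0.25 * colSums(log1p(outer(lambda^2, u^2)))
  ifelse(u == 0, 0.5 * sum(lambda) - 0.5 * q,
         sin(theta) / (u * exp(logrho)))
}

# Imhof's inversion integral, integrated piecewise over half-periods of the
# asymptotic oscillation (frequency q/2). The leading non-oscillatory region
# is summed directly; the alternating tail is accelerated by iterated
# averaging of its partial sums, giving far better than the requested
# tolerance with a few dozen terms.
imhof_pvalue <- function(q, lambda, tol = 1e-9) {
  h <- pi / max(q / 2, 1e-8)
  n_lead <- min(200L, ceiling((10 / min(lambda)) / h))
  I <- 0
  tail_terms <- numeric(0)
  for (j in seq_len(n_lead + 60L) - 1L) {
    tj <- stats::integrate(imhof_integrand, j * h, (j + 1) * h,
                           lambda = lambda, q = q,
                           rel.tol = 1e-10, abs.tol = 1e-13,
                           subdivisions = 500L)$value
    if (j < n_lead) I <- I + tj
    else {
      tail_terms <- c(tail_terms, tj)
      if (length(tail_terms) >= 12L && abs(tj) < tol / 100) break
    }
  }
  if (length(tail_terms)) {
    ps <- cumsum(tail_terms)
    while (length(ps) > 1L) ps <- (ps[-1L] + ps[-length(ps)]) / 2
    I <- I + ps
  }
  0.5 + I / pi
}

# Liu et al. moment-matching approximation to P(sum lambda_k chi2_1 > q).
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    a <- 1 / s1
    d <- 0
    l <- c2^3 / c3^2
  }
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  muX <- l + d; sigmaX <- sqrt(2) * a
  stats::pchisq((q - muQ) / sigmaQ * sigmaX + muX, df = l, ncp = d,
                lower.tail = FALSE)
}

#' Tail probability of a positive chi-square mixture
#'
#' Computes `p = P(sum_k lambda_k chi^2_1k > q)`, the null tail of the
#' weighted score statistic, by Davies-type numerical inversion of the
#' characteristic function (Imhof's integral, relative tolerance 1e-9).
#' Falls back to Liu-type moment matching if the inversion fails or returns
#' a value outside the valid range; the method actually used is reported.
#' Eigenvalues below `1e-10 * max` are truncated.
#'
#' @param q Observed statistic (>= 0).
#' @param eigenvalues Non-negative spectrum, not all zero.
#' @return List with `p` (in (0, 1]) and `method` (`"davies"` or
#'   `"moment_matching"`).
#' @examples
#' quadratic_form_pvalue(qchisq(0.95, 1), 1)  # p = 0.05
#' @export
quadratic_form_pvalue <- function(q, eigenvalues) {
  lambda <- eigenvalues[eigenvalues > 1e-10 * max(eigenvalues, 0)]
  if (length(lambda) == 0L) stop("eigenvalues must not be all zero")
  if (any(eigenvalues < 0)) stop("eigenvalues must be non-negative")
  if (q <= 0) return(list(p = 1, method = "davies"))
  p <- tryCatch(imhof_pvalue(q, lambda), error = function(e) NA_real_)
  if (is.finite(p) && p > 1e-12 && p <= 1 + 1e-9)
    return(list(p = min(p, 1), method = "davies"))
  list(p = min(max(liu_pvalue(q, lambda), .Machine$double.xmin), 1),
       method = "moment_matching")
}

#' Weighted SKAT-type score test for one variant set
#'
#' Computes the weighted quadratic-form statistic [skat_q()] and its
#' analytic p-value from the eigenvalue spectrum of the weighted,
#' covariate-projected kernel; optionally also a permutation p-value from
#' residual permutations.
#'
#' @inheritParams skat_q
#' @param cfg Optional [perm_config()]; when supplied, a permutation p-value
#'   (add-one convention) is computed alongside the analytic one.
#' @return List of class `rv_skat` with `q`, `p`, `method`, `spectrum`, and
#'   (when `cfg` is given) `p_permutation`.
#' @export
skat_test <- function(genotypes, weights, null, cfg = NULL) {
  G <- impute_mean_dosage(as_dosage_matrix(genotypes))
  q <- skat_q(G, weights, null)
  lambda <- if (all(weights == 0)) numeric(0)
            else kernel_spectrum(score_covariance(G, null), weights)
  if (length(lambda) == 0L)  # zero weights or monomorphic variants
    return(structure(list(q = q, p = 1, method = "davies",
                          spectrum = numeric(0)), class = "rv_skat"))
  pv <- quadratic_form_pvalue(q, lambda)
  out <- list(q = q, p = pv$p, method = pv$method, spectrum = lambda)
  if (!is.null(cfg)) {
    stopifnot(inherits(cfg, "perm_config"))
    B <- cfg$n_permutations
    qb <- with_seed(derive_seed(cfg$seed, "skat-perm"), {
      R <- vapply(seq_len(B), function(b) sample(null$residuals),
                  numeric(length(null$residuals)))
      colSums((weights^2) * crossprod(G, R)^2)
    })
    out$p_permutation <- (sum(qb >= q) + 1) / (B + 1)
    out$n_permutations <- B
  }
  structure(out, class = "rv_skat")
}

#' @export
print.rv_skat <- function(x, ...) {
  cat(sprintf("Weighted score test: Q = %.4g, p = %.4g (%s", x$q, x$p,
              x$method))
  if (!is.null(x$p_permutation))
    cat(sprintf("; permutation p = %.4g, B = %d", x$p_permutation,
                x$n_permutations))
  cat(")\n")
  invisible(x)
}

#' Combined rare/common weighted association test
#'
#' Partitions variants by minor-allele frequency at `maf_cutoff_rare`
#' (strict `<` = rare; default 0.1%), computes the weighted score statistic
#' and analytic p-value in each partition, and combines them through the
#' variance-standardized convex sum
#' `Q(rho) = rho * Q_rare / sd0(Q_rare) + (1 - rho) * Q_common / sd0(Q_common)`
#' over a grid of mixing weights `rho`. The combined p-value is the minimum
#' permutation p over the grid, corrected for the grid search by residual
#' permutation (min-p over each permuted dataset's own grid). If one
#' partition is empty the combined p degrades to the non-empty partition's
#' analytic p. When the null model has not converged, partition p-values are
#' taken from the permutation distribution instead of the analytic spectrum.
#'
#' @inheritParams skat_q
#' @param maf_cutoff_rare MAF boundary in (0, 0.5); variants with MAF
#'   strictly below it are "rare".
#' @param rho_grid Non-empty vector of mixing weights in `[0, 1]`.
#' @param cfg [perm_config()] governing the permutation correction.
#' @param maf Optional per-variant MAF vector overriding the sample MAF for
#'   the partition (e.g. reference-population frequencies).
#' @return An object of class `rv_common_rare`: list with `q_rare`,
#'   `q_common`, `p_rare`, `p_common`, `p_combined`, `p_rho` (observed
#'   permutation p per grid point), `rho_grid`, `rare_variant_ids`,
#'   `common_variant_ids`, `maf_cutoff_rare`, `method`, `n_permutations`,
#'   `seed`.
#' @export
common_rare_test <- function(genotypes, weights, null,
                             maf_cutoff_rare = 0.001,
                             rho_grid = c(0, 0.25, 0.5, 0.75, 1),
                             cfg = perm_config(2000L, seed = 1L),
                             maf = NULL) {
  stopifnot(inherits(null, "rv_null_model"), inherits(cfg, "perm_config"))
  if (length(rho_grid) == 0L || any(rho_grid < 0 | rho_grid > 1))
    stop("rho_grid must be a non-empty subset of [0, 1]")
  if (maf_cutoff_rare <= 0 || maf_cutoff_rare >= 0.5)
    stop("maf_cutoff_rare must lie in (0, 0.5)")
  gm <- if (inherits(genotypes, "genotype_matrix")) genotypes
        else genotype_matrix(genotypes)
  G <- impute_mean_dosage(gm$dosages)
  m <- ncol(G)
  if (m == 0L) stop("no variants to test")
  if (length(weights) != m) stop("one weight per variant is required")
  maf <- maf %||% gm$sample_mafs
  if (length(maf) != m) stop("one MAF per variant is required")
  rare <- maf < maf_cutoff_rare

  Sigma <- score_covariance(G, null)
  r <- null$residuals
  U <- drop(crossprod(G, r))

  part_stats <- function(idx) {
    if (!any(idx)) return(NULL)
    w <- weights[idx]
    q <- sum((w^2) * U[idx]^2)
    lambda <- if (all(w == 0)) numeric(0)
              else kernel_spectrum(Sigma[idx, idx, drop = FALSE], w)
    if (length(lambda) == 0L)  # zero weights or monomorphic variants
      return(list(q = q, p = 1, method = "davies", sd0 = NA_real_))
    pv <- quadratic_form_pvalue(q, lambda)
    list(q = q, p = pv$p, method = pv$method, sd0 = sqrt(2 * sum(lambda^2)))
  }
  sr <- part_stats(rare)
  sc <- part_stats(!rare)

  B <- cfg$n_permutations
  # permutation machinery: scaled partition statistics under residual shuffles
  perm_part_q <- function(idx, R) {
    if (!any(idx)) return(NULL)
    w2 <- weights[idx]^2
    colSums(w2 * crossprod(G[, idx, drop = FALSE], R)^2)
  }
  need_perm <- (!is.null(sr) && !is.null(sc)) || !null$converged
  qr_b <- qc_b <- NULL
  if (need_perm) {
    R <- with_seed(derive_seed(cfg$seed, "common-rare-perm"),
                   vapply(seq_len(B), function(b) sample(r),
                          numeric(length(r))))
    qr_b <- perm_part_q(rare, R)
    qc_b <- perm_part_q(!rare, R)
    if (!null$converged) {
      if (!is.null(sr)) {
        sr$p <- (sum(qr_b >= sr$q) + 1) / (B + 1)
        sr$method <- "permutation"
      }
      if (!is.null(sc)) {
        sc$p <- (sum(qc_b >= sc$q) + 1) / (B + 1)
        sc$method <- "permutation"
      }
    }
  }

  p_rho <- NULL
  if (!is.null(sr) && !is.null(sc)) {
    sd_r <- if (is.na(sr$sd0) || sr$sd0 == 0) stats::sd(qr_b) else sr$sd0
    sd_c <- if (is.na(sc$sd0) || sc$sd0 == 0) stats::sd(qc_b) else sc$sd0
    sd_r <- max(sd_r, .Machine$double.eps)
    sd_c <- max(sd_c, .Machine$double.eps)
    t_obs <- rho_grid * sr$q / sd_r + (1 - rho_grid) * sc$q / sd_c
    # B x n_rho matrix of permuted combined statistics
    Tb <- outer(qr_b / sd_r, rho_grid) + outer(qc_b / sd_c, 1 - rho_grid)
    # add-one p of the observed statistic at each rho
    p_rho <- (colSums(Tb >= rep(t_obs, each = B)) + 1) / (B + 1)
    # min-p over the grid for each permutation, each ranked against the others
    Pb <- apply(Tb, 2L, function(col)
      (length(col) - rank(col, ties.method = "min") + 1) / (B + 1))
    minp_b <- do.call(pmin, as.data.frame(Pb))
    p_combined <- (sum(minp_b <= min(p_rho)) + 1) / (B + 1)
    names(p_rho) <- paste0("rho=", rho_grid)
  } else {
    p_combined <- if (!is.null(sr)) sr$p else sc$p
  }

  structure(
    list(q_rare = if (is.null(sr)) NA_real_ else sr$q,
         q_common = if (is.null(sc)) NA_real_ else sc$q,
         p_rare = if (is.null(sr)) NA_real_ else sr$p,
         p_common = if (is.null(sc)) NA_real_ else sc$p,
         p_combined = p_combined,
         p_rho = p_rho,
         rho_grid = rho_grid,
         rare_variant_ids = gm$variant_ids[rare],
         common_variant_ids = gm$variant_ids[!rare],
         maf_cutoff_rare = maf_cutoff_rare,
         method = c(rare = if (is.null(sr)) NA_character_ else sr$method,
                    common = if (is.null(sc)) NA_character_ else sc$method),
         n_permutations = if (need_perm) B else 0L,
         seed = cfg$seed),
    class = "rv_common_rare")
}

#' @export
print.rv_common_rare <- function(x, ...) {
  cat("Combined rare/common weighted association test\n")
  cat(sprintf("  rare (MAF < %g): %d variant(s), Q = %.4g, p = %.4g\n",
              x$maf_cutoff_rare, length(x$rare_variant_ids), x$q_rare,
              x$p_rare))
  cat(sprintf("  common:          %d variant(s), Q = %.4g, p = %.4g\n",
              length(x$common_variant_ids), x$q_common, x$p_common))
  cat(sprintf("  combined p = %.4g", x$p_combined))
  if (x$n_permutations > 0)
    cat(sprintf("  (min-p over rho {%s}, B = %d)",
                paste(x$rho_grid, collapse = ", "), x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' `alpha / n_tests`; e.g. a 0.05 family-wise level over 25,000 genes gives
#' the exome-wide threshold 2e-6.
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Positive number of tests.
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_tests < 1) stop("n_tests must be a positive integer")
  alpha / n_tests
}
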