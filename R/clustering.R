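#' Permutation configuration
#'
#' @param n_permutations Number of null draws B (default 100,000, the
#'   convention for single-gene clustering analyses at this scale).
#' @param seed Integer seed; identical configuration implies identical
#'   results.
#' @param sampling `"distinct_positions"` draws each null set as n distinct
#'   integer positions (matching observed data, where positions are unique
#'   sites); `"with_replacement"` allows duplicates and redraws any set with
#'   a zero pairwise distance, since the geometric mean would collapse to 0.
#' @return An object of class `perm_config`.
#' @export
perm_config <- function(n_permutations = 100000L, seed = 1L,
                        sampling = c("distinct_positions", "with_replacement")) {
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L)
    stop("n_permutations must be a positive integer")
  sampling <- match.arg(sampling)
  structure(list(n_permutations = n_permutations, seed = as.integer(seed),
                 sampling = sampling),
            class = "perm_config")
}

#' Normalized geometric-mean pairwise distance
#'
#' The spatial-clustering statistic: the geometric mean of the absolute
#' distances between all n(n-1)/2 pairs of variant CDS positions, divided by
#' the CDS length L. Dimensionless; small values indicate clustering. The
#' product is accumulated on the log scale for numerical stability.
#'
#' @param positions Integer vector (>= 2) of CDS positions in `[1, L]`.
#' @param cds_length_bp CDS length L in base pairs.
#' @return The statistic, a non-negative scalar.
#' @examples
#' geometric_mean_pairwise_distance(c(100, 200), 1000)  # 0.1
#' @export
geometric_mean_pairwise_distance <- function(positions, cds_length_bp) {
  positions <- as.numeric(positions)
  n <- length(positions)
  if (n < 2L)
    stop("at least 2 positions are required")
  if (any(positions < 1 | positions > cds_length_bp))
    stop("positions must lie in [1, cds_length_bp]")
  ij <- utils::combn(n, 2L)
  d <- abs(positions[ij[1L, ]] - positions[ij[2L, ]])
  if (any(d == 0))
    stop("duplicate positions give a zero pairwise distance; ",
         "the geometric mean is undefined (0)")
  exp(mean(log(d))) / cds_length_bp
}

# Draw B null position sets (rows: sets) under the configured sampling.
# distinct_positions redraws are unnecessary (sample.int without replacement);
# with_replacement redraws sets containing duplicates only where requested.
draw_null_positions <- function(n, L, B, sampling, dedupe = FALSE) {
  if (sampling == "distinct_positions") {
    if (n > L) stop("cannot draw ", n, " distinct positions from [1, ", L, "]")
    t(vapply(seq_len(B), function(i) sample.int(L, n), integer(n)))
  } else {
    M <- matrix(sample.int(L, n * B, replace = TRUE), nrow = B)
    if (dedupe) {
      bad <- apply(M, 1L, anyDuplicated) > 0L
      while (any(bad)) {
        M[bad, ] <- matrix(sample.int(L, n * sum(bad), replace = TRUE),
                           nrow = sum(bad))
        bad <- apply(M, 1L, anyDuplicated) > 0L
      }
    }
    M
  }
}

# Clustering statistic for each row of a position matrix, chunked to bound
# the size of the pairwise-distance intermediate.
row_cluster_stat <- function(M, L, chunk = 20000L) {
  n <- ncol(M)
  ij <- utils::combn(n, 2L)
  out <- numeric(nrow(M))
  for (idx in split(seq_len(nrow(M)), ceiling(seq_len(nrow(M)) / chunk))) {
    D <- abs(M[idx, ij[1L, ], drop = FALSE] - M[idx, ij[2L, ], drop = FALSE])
    out[idx] <- exp(rowMeans(log(D))) / L
  }
  out
}

#' Permutation test for spatial clustering of variants along the CDS
#'
#' Compares the observed normalized geometric-mean pairwise distance of the
#' variant positions against B null sets of n positions drawn uniformly from
#' `[1, L]`. Smaller statistics mean tighter clustering, so the one-sided
#' empirical p-value counts null draws with statistic less than or equal to
#' the observed one, with the add-one convention
#' `p = (r + 1) / (B + 1)` (never exactly zero).
#'
#' @param positions Integer vector of CDS positions (>= 2, distinct).
#' @param model A [gene_model()] supplying the CDS length.
#' @param cfg A [perm_config()].
#' @return An object of class `rv_perm_test`: a list with
#'   `observed_statistic`, `empirical_p`, `n_permutations`, `n_as_extreme`,
#'   `seed`, `sampling`, `n_positions`, `cds_length_bp`.
#' @examples
#' m <- pam_gene_model()
#' clustering_permutation_test(c(100, 110, 120, 2500), m,
#'                             perm_config(999, seed = 7))
#' @export
clustering_permutation_test <- function(positions, model,
                                        cfg = perm_config()) {
  stopifnot(inherits(model, "gene_model"), inherits(cfg, "perm_config"))
  L <- model$cds_length_bp
  obs <- geometric_mean_pairwise_distance(positions, L)
  n <- length(positions)
  B <- cfg$n_permutations
  if (cfg$sampling == "distinct_positions" && anyDuplicated(positions))
    stop("positions must be distinct under distinct_positions sampling")
  r <- with_seed(derive_seed(cfg$seed, "clustering"), {
    r <- 0L
    done <- 0L
    while (done < B) {
      b <- min(20000L, B - done)
      M <- draw_null_positions(n, L, b, cfg$sampling,
                               dedupe = cfg$sampling == "with_replacement")
      r <- r + sum(row_cluster_stat(M, L) <= obs)
      done <- done + b
    }
    r
  })
  structure(
    list(observed_statistic = obs,
         empirical_p = (r + 1) / (B + 1),
         n_permutations = B,
         n_as_extreme = as.integer(r),
         seed = cfg$seed,
         sampling = cfg$sampling,
         n_positions = n,
         cds_length_bp = L),
    class = "rv_perm_test")
}

#' @export
print.rv_perm_test <- function(x, ...) {
  cat("Spatial-clustering permutation test\n")
  cat(sprintf("  %d positions on a %d bp CDS; B = %d (%s sampling)\n",
              x$n_positions, x$cds_length_bp, x$n_permutations, x$sampling))
  cat(sprintf("  observed statistic = %.6f\n", x$observed_statistic))
  cat(sprintf("  empirical p = %.4g  (%d of %d null draws as clustered)\n",
              x$empirical_p, x$n_as_extreme, x$n_permutations))
  invisible(x)
}

#' Per-domain variant-count permutation test
#'
#' Converts each protein domain to its CDS span (see
#' [domain_cds_intervals()]), counts the observed variants per domain, and
#' compares each count against the counts in B uniform null position sets.
#' One-sided for enrichment: `p = (#{draws with count >= observed} + 1) /
#' (B + 1)` per domain.
#'
#' @inheritParams clustering_permutation_test
#' @return An object of class `rv_domain_test`: a data.frame with one row per
#'   domain (`domain`, `span_bp`, `expected_fraction`, `observed`,
#'   `expected`, `obs_over_exp`, `n_as_extreme`, `empirical_p`) plus
#'   attributes `n_permutations`, `seed`, `sampling`.
#' @export
domain_count_permutation_test <- function(positions, model,
                                          cfg = perm_config()) {
  stopifnot(inherits(model, "gene_model"), inherits(cfg, "perm_config"))
  L <- model$cds_length_bp
  positions <- as.integer(positions)
  if (length(positions) < 1L) stop("at least 1 position is required")
  if (any(positions < 1L | positions > L))
    stop("positions must lie in [1, ", L, "]")
  iv <- domain_cds_intervals(model)
  n <- length(positions)
  B <- cfg$n_permutations
  count_in <- function(M) {
    # M: B x n matrix -> B x ndomain count matrix
    matrix(vapply(seq_len(nrow(iv)), function(k)
      rowSums(M >= iv$start_bp[k] & M <= iv$end_bp[k]),
      numeric(nrow(M))), nrow = nrow(M))
  }
  obs <- as.vector(count_in(matrix(positions, nrow = 1L)))
  r <- with_seed(derive_seed(cfg$seed, "domain-count"), {
    r <- numeric(nrow(iv))
    done <- 0L
    while (done < B) {
      b <- min(20000L, B - done)
      M <- draw_null_positions(n, L, b, cfg$sampling,
                               dedupe = cfg$sampling == "with_replacement")
      cnt <- count_in(M)
      r <- r + colSums(cnt >= rep(obs, each = b))
      done <- done + b
    }
    r
  })
  frac <- (iv$end_bp - iv$start_bp + 1L) / L
  out <- data.frame(
    domain = iv$name,
    span_bp = iv$end_bp - iv$start_bp + 1L,
    expected_fraction = frac,
    observed = obs,
    expected = n * frac,
    obs_over_exp = obs / (n * frac),
    n_as_extreme = as.integer(r),
    empirical_p = (r + 1) / (B + 1),
    stringsAsFactors = FALSE)
  structure(out, class = c("rv_domain_test", "data.frame"),
            n_permutations = B, seed = cfg$seed, sampling = cfg$sampling)
}

#' @export
print.rv_domain_test <- function(x, ...) {
  cat("Per-domain variant-count permutation test (B =",
      attr(x, "n_permutations"), ")\n")
  df <- as.data.frame(x)
  df$expected <- round(df$expected, 2)
  df$obs_over_exp <- round(df$obs_over_exp, 2)
  df$expected_fraction <- round(df$expected_fraction, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
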