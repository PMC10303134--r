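#' Simulation specification
#'
#' Defines the synthetic inputs for desk-scale testing of the analyses.
#' Genotypes are independent Hardy-Weinberg draws at the stated minor-allele
#' frequencies; binary phenotypes follow a logistic model whose per-allele
#' log-odds are proportional to each variant's severity weight; variant
#' positions are either uniform over the CDS (the clustering null) or
#' concentrated around a few cluster centers. Defaults are desk-scale
#' (thousands of individuals, tens of variants), standing in for
#' biobank-scale cohorts whose structure they emulate.
#'
#' @param n_individuals Number of individuals.
#' @param variant_mafs Vector of minor-allele frequencies, each in (0, 0.5).
#' @param position_mode `"uniform"` or `"clustered"`.
#' @param n_clusters,cluster_spread_bp Cluster geometry for
#'   `position_mode = "clustered"`: centers are uniform over the CDS
#'   (placed so the window fits inside it) and members fall at
#'   center +/- spread, deduplicated by redraw.
#' @param effect_model `"null"` (no genotype effect) or
#'   `"weight_proportional"`.
#' @param beta_scale Log-odds per severity-weight unit per allele (only used
#'   under `"weight_proportional"`).
#' @param baseline_prevalence Case probability at zero genotype burden, in
#'   (0, 1).
#' @param seed Master integer seed; every generator derives its own stream
#'   from it.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(n_individuals = 2000L,
                            variant_mafs = c(0.0005, 0.001, 0.005, 0.01,
                                             0.05, 0.1, 0.2),
                            position_mode = c("uniform", "clustered"),
                            n_clusters = 1L, cluster_spread_bp = 10L,
                            effect_model = c("null", "weight_proportional"),
                            beta_scale = 0, baseline_prevalence = 0.1,
                            seed = 1L) {
  position_mode <- match.arg(position_mode)
  effect_model <- match.arg(effect_model)
  if (any(variant_mafs <= 0 | variant_mafs >= 0.5))
    stop("variant_mafs must lie strictly in (0, 0.5)")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("baseline_prevalence must lie in (0, 1)")
  if (n_individuals < 1L) stop("n_individuals must be positive")
  structure(list(n_individuals = as.integer(n_individuals),
                 variant_mafs = variant_mafs,
                 position_mode = position_mode,
                 n_clusters = as.integer(n_clusters),
                 cluster_spread_bp = as.integer(cluster_spread_bp),
                 effect_model = effect_model,
                 beta_scale = beta_scale,
                 baseline_prevalence = baseline_prevalence,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate variant CDS positions
#'
#' Uniform mode draws distinct integer positions uniformly from the CDS
#' (the clustering test's null); clustered mode draws cluster centers
#' uniformly among positions whose `+/- spread` window lies inside the CDS,
#' then members at center plus a uniform offset in `[-spread, spread]`,
#' redrawing duplicates.
#'
#' @param n Number of positions.
#' @param spec A [simulation_spec()].
#' @param model A [gene_model()].
#' @return Sorted integer vector of n distinct CDS positions.
#' @export
simulate_positions <- function(n, spec, model) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(model, "gene_model"))
  L <- model$cds_length_bp
  n <- as.integer(n)
  if (n > L) stop("cannot place ", n, " distinct positions on a ", L, " bp CDS")
  with_seed(derive_seed(spec$seed, "positions"), {
    if (spec$position_mode == "uniform") {
      sort(sample.int(L, n))
    } else {
      spread <- spec$cluster_spread_bp
      if ((2L * spread + 1L) * spec$n_clusters < n)
        stop("clusters too narrow to hold ", n, " distinct positions")
      if (L < 2L * spread + 1L)
        stop("cluster_spread_bp too large for the CDS")
      # centers placed so the +/- spread window always fits inside the CDS,
      # keeping the per-cluster support at its full 2*spread + 1 positions
      centers <- sample.int(L - 2L * spread, spec$n_clusters,
                            replace = TRUE) + spread
      pos <- integer(0)
      while (length(pos) < n) {
        need <- n - length(pos)
        cand <- centers[sample.int(length(centers), need, replace = TRUE)] +
          sample.int(2L * spread + 1L, need, replace = TRUE) - spread - 1L
        pos <- unique(c(pos, cand))
      }
      sort(pos[seq_len(n)])
    }
  })
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Independent `Binomial(2, maf)` dosages per individual and variant;
#' bit-identical under the same spec (the genotype stream is independent of
#' the other generators).
#'
#' @param spec A [simulation_spec()].
#' @return A [genotype_matrix()] of dimension
#'   `n_individuals x length(variant_mafs)`.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_individuals
  mafs <- spec$variant_mafs
  G <- with_seed(derive_seed(spec$seed, "genotypes"), {
    vapply(mafs, function(p) stats::rbinom(n, 2L, p), numeric(n))
  })
  genotype_matrix(matrix(G, nrow = n))
}

#' Simulate binary phenotypes under a logistic burden model
#'
#' `logit P(case_i) = logit(prevalence) + beta_scale * sum_j w_j g_ij`.
#' With `beta_scale = 0` (or under `effect_model = "null"`) this reduces to
#' independent `Bernoulli(prevalence)` draws regardless of genotype.
#'
#' @param genotypes A [genotype_matrix()] or dosage matrix.
#' @param weights Per-variant severity weights.
#' @param spec A [simulation_spec()].
#' @return Integer 0/1 phenotype vector.
#' @export
simulate_phenotypes <- function(genotypes, weights, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  G <- as_dosage_matrix(genotypes)
  if (ncol(G) != length(weights)) stop("one weight per variant is required")
  beta <- if (spec$effect_model == "null") 0 else spec$beta_scale
  eta <- stats::qlogis(spec$baseline_prevalence) +
    beta * drop(G %*% weights)
  with_seed(derive_seed(spec$seed, "phenotypes"), {
    as.integer(stats::runif(nrow(G)) < stats::plogis(eta))
  })
}

#' Simulate cohort and control allele counts
#'
#' Cohort alternate alleles are drawn `Binomial(cohort_alleles,
#' enrichment_factor * control_maf)` and control alternate alleles
#' `Binomial(control_alleles, control_maf)`; `enrichment_factor = 1` is the
#' null of [allele_count_test()].
#'
#' @param enrichment_factor Multiplicative cohort enrichment (>= 0);
#'   `enrichment_factor * control_maf` must not exceed 1.
#' @param control_maf Control allele frequency in (0, 1).
#' @param cohort_alleles,control_alleles Total allele numbers.
#' @param seed Integer seed.
#' @return List with elements `cohort` and `controls`, both
#'   [allele_counts()].
#' @export
simulate_cohort_counts <- function(enrichment_factor, control_maf,
                                   cohort_alleles, control_alleles, seed = 1L) {
  if (control_maf <= 0 || control_maf >= 1)
    stop("control_maf must lie in (0, 1)")
  if (enrichment_factor < 0 || enrichment_factor * control_maf > 1)
    stop("enrichment_factor * control_maf must lie in [0, 1]")
  with_seed(derive_seed(seed, "cohort-counts"), {
    list(cohort = allele_counts(
           stats::rbinom(1L, cohort_alleles, enrichment_factor * control_maf),
           cohort_alleles),
         controls = allele_counts(
           stats::rbinom(1L, control_alleles, control_maf),
           control_alleles))
  })
}
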