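#' Read a pipeline configuration
#'
#' A single JSON document drives [run_pipeline()]:
#' ```
#' {
#'   "variants": "variants.tsv",        // required
#'   "gene_model": "model.json",        // default: packaged PAM model
#'   "stages": ["prioritize", "cluster", "weigh", "enrich", "associate"],
#'   "seed": 1, "n_permutations": 100000, "sampling": "distinct_positions",
#'   "maf_threshold_pct": 1.0, "cadd_threshold": 15,
#'   "cohort_an": 652, "control_an": 152312,   // for the enrich stage
#'   "genotypes": "dosages.tsv",        // TSV or .vcf, for associate
#'   "phenotypes": "phenotypes.tsv",
#'   "maf_cutoff_rare": 0.001
#' }
#' ```
#' One master seed drives every stage; per-stage streams are derived from it
#' deterministically, so results are reproducible bit-for-bit.
#'
#' @param path JSON path.
#' @return Named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  as_pipeline_config(cfg, base_dir = dirname(path))
}

#' @rdname read_pipeline_config
#' @param cfg Named list of configuration values.
#' @param base_dir Directory against which relative input paths resolve.
#' @export
as_pipeline_config <- function(cfg, base_dir = ".") {
  defaults <- list(
    stages = c("prioritize", "cluster", "weigh", "enrich", "associate"),
    gene_model = system.file("extdata", "pam_gene_model.json",
                             package = "rvgene", mustWork = TRUE),
    weight_scheme = system.file("extdata", "default_weight_scheme.json",
                                package = "rvgene", mustWork = TRUE),
    seed = 1L, n_permutations = 100000L, sampling = "distinct_positions",
    maf_threshold_pct = 1.0, cadd_threshold = 15,
    cohort_an = NULL, control_an = NULL,
    genotypes = NULL, phenotypes = NULL,
    maf_cutoff_rare = 0.001, rho_grid = c(0, 0.25, 0.5, 0.75, 1),
    assoc_permutations = 2000L)
  unknown <- setdiff(names(cfg), c(names(defaults), "variants"))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg)
  if (is.null(out$variants)) stop("configuration lacks 'variants'")
  for (key in c("variants", "gene_model", "weight_scheme", "genotypes",
                "phenotypes")) {
    if (!is.null(out[[key]]) && !file.exists(out[[key]])) {
      cand <- file.path(base_dir, out[[key]])
      if (file.exists(cand)) out[[key]] <- cand
    }
  }
  structure(out, class = c("pipeline_config", "list"))
}

log_msg <- function(...) message("[rvgene] ", ...)

#' Run the end-to-end analysis pipeline
#'
#' Chains the analyses in dependency order over a configuration (see
#' [read_pipeline_config()]): variant reading/annotation, prioritization,
#' spatial clustering and per-domain counts (coding variants only),
#' severity weighting, cohort-versus-population enrichment, and the
#' rare/common weighted association test. Each enabled stage writes its
#' result under `out_dir` (TSV for tables, JSON for test results) and a
#' `manifest.json` records the configuration snapshot, input MD5 checksums,
#' seed, package version and timestamp. Stage errors are collected per
#' stage; the run fails (error) only after all stages have been attempted,
#' naming each failed stage. Logging goes to stderr via `message()`;
#' machine-readable outputs never mix with logs.
#'
#' @param config A `pipeline_config`, a named list, or a JSON path.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list of per-stage results with a `status`
#'   element (`"ok"`, `"skipped"`, or `"error: ..."` per stage).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- as_pipeline_config(config)
  stages <- config$stages
  known_stages <- c("prioritize", "cluster", "weigh", "enrich", "associate")
  if (length(bad <- setdiff(stages, known_stages)))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  # configuration errors surface before any compute
  if ("associate" %in% stages &&
      (is.null(config$genotypes) || is.null(config$phenotypes)))
    stop("stage 'associate' requires 'genotypes' and 'phenotypes' inputs")
  if ("enrich" %in% stages &&
      (is.null(config$cohort_an) || is.null(config$control_an)))
    stop("stage 'enrich' requires 'cohort_an' and 'control_an'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  status <- stats::setNames(rep("skipped", length(known_stages)), known_stages)
  results <- list()
  model <- read_gene_model(config$gene_model)
  scheme <- read_weight_scheme(config$weight_scheme)
  variants <- read_variant_table(config$variants)
  log_msg("read ", nrow(variants), " variants from ", config$variants)

  run_stage <- function(name, fun) {
    if (!name %in% stages) return()
    log_msg("stage: ", name)
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      status[[name]] <<- paste0("error: ", conditionMessage(res))
      log_msg("stage ", name, " FAILED: ", conditionMessage(res))
    } else {
      status[[name]] <<- "ok"
      results[[name]] <<- res
    }
  }

  run_stage("prioritize", function() {
    ann <- flag_rare_deleterious(
      variants, prioritization_config(config$maf_threshold_pct,
                                      config$cadd_threshold))
    write_variant_table(ann, file.path(out_dir, "prioritized.tsv"))
    ann
  })

  run_stage("cluster", function() {
    coding <- variants[!variants$utr3 & variants$anchor_bp > 0, , drop = FALSE]
    cfg <- perm_config(config$n_permutations, config$seed, config$sampling)
    ct <- clustering_permutation_test(coding$anchor_bp, model, cfg)
    dt <- domain_count_permutation_test(coding$anchor_bp, model, cfg)
    jsonlite::write_json(
      list(observed_statistic = ct$observed_statistic,
           empirical_p = ct$empirical_p,
           n_permutations = ct$n_permutations,
           n_as_extreme = ct$n_as_extreme,
           seed = ct$seed, sampling = ct$sampling,
           n_positions = ct$n_positions),
      file.path(out_dir, "clustering.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(as.data.frame(dt),
                       file.path(out_dir, "domain_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(clustering = ct, domain_counts = dt)
  })

  run_stage("weigh", function() {
    w <- weigh_variants(variants, scheme)
    write_variant_table(w, file.path(out_dir, "weighted.tsv"))
    w
  })

  run_stage("enrich", function() {
    e <- enrich_variants(variants, config$cohort_an, config$control_an)
    write_variant_table(e, file.path(out_dir, "enrichment.tsv"))
    e
  })

  run_stage("associate", function() {
    gm <- if (grepl("\\.vcf(\\.gz)?$", config$genotypes))
      read_genotypes_vcf(config$genotypes)
    else read_dosage_tsv(config$genotypes)
    ph <- read_phenotypes(config$phenotypes, sample_ids = gm$sample_ids)
    null <- fit_null_binary(ph$phenotypes, ph$covariates)
    vmatch <- match(gm$variant_ids, variants$hgvs_c)
    w <- if (anyNA(vmatch)) {
      log_msg("genotype variant ids not in the variant table; ",
              "using unit weights")
      rep(1, length(gm$variant_ids))
    } else weigh_variants(variants[vmatch, , drop = FALSE], scheme)$weight
    res <- common_rare_test(
      gm, w, null, maf_cutoff_rare = config$maf_cutoff_rare,
      rho_grid = config$rho_grid,
      cfg = perm_config(config$assoc_permutations, config$seed))
    jsonlite::write_json(
      list(q_rare = res$q_rare, q_common = res$q_common,
           p_rare = res$p_rare, p_common = res$p_common,
           p_combined = res$p_combined,
           rho_grid = res$rho_grid,
           rare_variant_ids = res$rare_variant_ids,
           common_variant_ids = res$common_variant_ids,
           maf_cutoff_rare = res$maf_cutoff_rare,
           n_permutations = res$n_permutations, seed = res$seed),
      file.path(out_dir, "association.json"), auto_unbox = TRUE, digits = NA)
    res
  })

  inputs <- Filter(Negate(is.null),
                   config[c("variants", "gene_model", "weight_scheme",
                            "genotypes", "phenotypes")])
  manifest <- list(
    tool = "rvgene",
    version = as.character(utils::packageVersion("rvgene")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    input_checksums = as.list(tools::md5sum(unlist(inputs))),
    stage_status = as.list(status))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  failed <- names(status)[startsWith(status, "error")]
  if (length(failed))
    stop("pipeline stage(s) failed: ", paste(failed, collapse = ", "))
  invisible(c(results, list(status = status)))
}
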