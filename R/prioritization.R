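#' Combine per-tool pathogenicity verdicts into a classification
#'
#' Takes the counts of (pathogenic, uncertain, benign) verdicts from a panel
#' of prediction tools and returns a single label. Default `"plurality"`
#' rule: the category with a strict plurality wins; a tie, or a plurality of
#' uncertain verdicts, yields `"vus"`. Commercial aggregators weight
#' individual tools, so printed labels in published tables cannot always be
#' reproduced from the counts alone; the rule is therefore injectable.
#'
#' @param n_pathogenic,n_uncertain,n_benign Non-negative verdict counts
#'   (vectors allowed, recycled to a common length).
#' @param rule Either `"plurality"` or a function
#'   `(n_pathogenic, n_uncertain, n_benign) -> label` applied per variant.
#' @return Character vector with levels `likely_pathogenic`, `vus`,
#'   `likely_benign`.
#' @examples
#' combine_verdicts(10, 9, 0)   # likely_pathogenic
#' combine_verdicts(0, 11, 7)   # vus
#' combine_verdicts(0, 3, 16)   # likely_benign
#' @export
combine_verdicts <- function(n_pathogenic, n_uncertain, n_benign,
                             rule = "plurality") {
  n <- max(length(n_pathogenic), length(n_uncertain), length(n_benign))
  np <- rep_len(as.integer(n_pathogenic), n)
  nu <- rep_len(as.integer(n_uncertain), n)
  nb <- rep_len(as.integer(n_benign), n)
  if (any(c(np, nu, nb) < 0, na.rm = TRUE)) stop("verdict counts must be >= 0")
  if (any(np + nu + nb == 0L, na.rm = TRUE))
    stop("at least one verdict is required")
  if (is.function(rule))
    return(vapply(seq_len(n), function(i) rule(np[i], nu[i], nb[i]),
                  character(1)))
  if (!identical(rule, "plurality")) stop("unknown rule")
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (anyNA(c(np[i], nu[i], nb[i]))) next
    cnt <- c(likely_pathogenic = np[i], vus = nu[i], likely_benign = nb[i])
    top <- which(cnt == max(cnt))
    out[i] <- if (length(top) > 1L || names(top) == "vus") "vus"
              else names(top)
  }
  out
}

#' Triage configuration
#'
#' @param maf_threshold_pct Control-population MAF threshold in percent
#'   (default 1).
#' @param cadd_threshold CADD_PHRED threshold (default 15) used when tool
#'   verdicts are absent.
#' @param rule Verdict-combination rule passed to [combine_verdicts()].
#' @return A `prioritization_config` object.
#' @export
prioritization_config <- function(maf_threshold_pct = 1.0,
                                  cadd_threshold = 15, rule = "plurality") {
  if (maf_threshold_pct <= 0 || cadd_threshold <= 0)
    stop("thresholds must be positive")
  structure(list(maf_threshold_pct = maf_threshold_pct,
                 cadd_threshold = cadd_threshold, rule = rule),
            class = "prioritization_config")
}

#' Flag rare or predicted-deleterious variants
#'
#' A variant is flagged when ANY of the non-mutually-exclusive criteria
#' holds: (1) rare — control MAF below the threshold; (2) in-silico — the
#' verdict classification is `likely_pathogenic`, or CADD_PHRED meets the
#' threshold when verdicts are absent, or a splice/regulatory in-silico
#' effect is annotated; (3) published functional evidence of pathogenicity.
#' Missing fields silently skip their criterion (with a `notes` entry), so
#' adding information can only add reasons, never remove the flag.
#'
#' @param variants Variant table (see [read_variant_table()]); consulted
#'   columns: `control_maf_pct`, `verdict_pathogenic`, `verdict_uncertain`,
#'   `verdict_benign`, `cadd_phred`, `splice_or_regulatory_effect`,
#'   `published_functional_evidence`.
#' @param cfg A [prioritization_config()].
#' @return The table with columns `flagged` (logical), `flag_reasons`
#'   (comma-separated among `rare`, `in-silico`, `functional-evidence`) and
#'   `classification` (from [combine_verdicts()], NA when verdicts absent).
#' @export
flag_rare_deleterious <- function(variants, cfg = prioritization_config()) {
  stopifnot(inherits(cfg, "prioritization_config"))
  n <- nrow(variants)
  col <- function(nm, default) {
    if (nm %in% names(variants)) variants[[nm]] else rep(default, n)
  }
  control_maf <- col("control_maf_pct", NA_real_)
  np <- col("verdict_pathogenic", NA_integer_)
  nu <- col("verdict_uncertain", NA_integer_)
  nb <- col("verdict_benign", NA_integer_)
  cadd <- col("cadd_phred", NA_real_)
  splice_reg <- col("splice_or_regulatory_effect", NA)
  pub <- col("published_functional_evidence", NA)

  has_verdicts <- !is.na(np) & !is.na(nu) & !is.na(nb) & (np + nu + nb > 0L)
  classification <- rep(NA_character_, n)
  if (any(has_verdicts))
    classification[has_verdicts] <- combine_verdicts(
      np[has_verdicts], nu[has_verdicts], nb[has_verdicts], rule = cfg$rule)

  rare <- !is.na(control_maf) & control_maf < cfg$maf_threshold_pct
  insilico <- (has_verdicts & classification == "likely_pathogenic") |
    (!has_verdicts & !is.na(cadd) & cadd >= cfg$cadd_threshold) |
    (!is.na(splice_reg) & splice_reg)
  insilico[is.na(insilico)] <- FALSE
  functional <- !is.na(pub) & pub

  reasons <- vapply(seq_len(n), function(i)
    paste(c(if (rare[i]) "rare",
            if (insilico[i]) "in-silico",
            if (functional[i]) "functional-evidence"),
          collapse = ","), character(1))
  skipped <- vapply(seq_len(n), function(i)
    paste(c(if (is.na(control_maf[i])) "control-maf-missing",
            if (!has_verdicts[i] && is.na(cadd[i])) "no-verdicts-or-cadd"),
          collapse = ","), character(1))
  if (any(nzchar(skipped)))
    message(sum(nzchar(skipped)),
            " variant(s) had criteria skipped for missing fields")

  variants$classification <- classification
  variants$flagged <- rare | insilico | functional
  variants$flag_reasons <- reasons
  variants$flag_notes <- skipped
  variants
}

#' Prioritize variants in a table
#'
#' Convenience wrapper: applies [flag_rare_deleterious()] and returns the
#' flagged subset (the full annotated table is available as attribute
#' `"all"`).
#'
#' @inheritParams flag_rare_deleterious
#' @return The flagged rows.
#' @export
prioritize_variants <- function(variants, cfg = prioritization_config()) {
  ann <- flag_rare_deleterious(variants, cfg)
  out <- ann[ann$flagged, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- ann
  out
}
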