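#' Carrier frequency as a printed percentage
#'
#' `100 * carriers / denominator`, rounded half-up to 2 decimal places (the
#' convention used when reporting cohort carrier frequencies, e.g.
#' 1/18 = 5.56%).
#'
#' @param carriers Non-negative carrier count.
#' @param denominator Positive denominator (individuals or kindreds).
#' @return Percentage rounded to 2 decimals.
#' @examples
#' carrier_frequency(1, 18)   # 5.56
#' carrier_frequency(2, 81)   # 2.47
#' @export
carrier_frequency <- function(carriers, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(carriers < 0) || any(carriers > denominator))
    stop("carriers must lie in [0, denominator]")
  x <- 100 * carriers / denominator
  floor(x * 100 + 0.5) / 100   # half-up, unlike round()'s round-half-even
}

#' Allele counts helper
#'
#' @param alt_alleles Non-negative count of alternate alleles observed.
#' @param total_alleles Positive total allele number (AN).
#' @return An `allele_counts` object.
#' @export
allele_counts <- function(alt_alleles, total_alleles) {
  alt_alleles <- as.integer(alt_alleles)
  total_alleles <- as.integer(total_alleles)
  if (total_alleles <= 0L) stop("total_alleles must be positive")
  if (alt_alleles < 0L || alt_alleles > total_alleles)
    stop("alt_alleles must lie in [0, total_alleles]")
  structure(list(alt_alleles = alt_alleles, total_alleles = total_alleles),
            class = "allele_counts")
}

#' Convert a printed MAF percentage to allele counts
#'
#' Reference tables often print control MAFs without allele numbers; this
#' helper reconstructs integer counts under an explicitly assumed total
#' allele number, with the assumption attached so it is never silent.
#'
#' @param maf_pct MAF in percent.
#' @param assumed_an Assumed total allele number.
#' @return An [allele_counts()] with attribute `assumed_an = TRUE`.
#' @export
maf_to_counts <- function(maf_pct, assumed_an) {
  if (maf_pct < 0 || maf_pct > 100) stop("maf_pct must lie in [0, 100]")
  k <- as.integer(round(maf_pct / 100 * assumed_an))
  out <- allele_counts(k, assumed_an)
  attr(out, "assumed_an") <- TRUE
  out
}

#' Cohort-versus-population allele-count enrichment test
#'
#' Builds the 2x2 table (alt/ref alleles by cohort/controls) and tests
#' whether the cohort allele frequency differs from the control frequency.
#' The chi-square test (1 df, no continuity correction) is used when all
#' four expected cell counts are at least 5; otherwise the two-sided
#' Fisher's exact test (point-probability method: summing tables whose
#' probability does not exceed the observed one).
#'
#' @param cohort,controls [allele_counts()] objects (or 2-element
#'   `c(alt, total)` vectors).
#' @return An `rv_enrichment` list: `p_value`, `test_used`
#'   (`"fisher_exact"` or `"chi_square"`), `odds_ratio` (sample odds ratio;
#'   `NA` with `or_undefined = TRUE` for degenerate margins), and `table`.
#' @examples
#' allele_count_test(allele_counts(2, 652), allele_counts(11, 152312))
#' @export
allele_count_test <- function(cohort, controls) {
  as_ac <- function(x) {
    if (inherits(x, "allele_counts")) x
    else allele_counts(x[[1L]], x[[2L]])
  }
  cohort <- as_ac(cohort); controls <- as_ac(controls)
  tab <- matrix(c(cohort$alt_alleles, cohort$total_alleles - cohort$alt_alleles,
                  controls$alt_alleles,
                  controls$total_alleles - controls$alt_alleles),
                nrow = 2L,
                dimnames = list(c("alt", "ref"), c("cohort", "controls")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  or_undefined <- !is.finite(or)
  if (any(rowSums(tab) == 0)) {
    # no alt (or no ref) allele in either group: nothing to compare
    return(structure(list(p_value = 1, test_used = "fisher_exact",
                          odds_ratio = NA_real_, or_undefined = TRUE,
                          table = tab),
                     class = "rv_enrichment"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
    test_used <- "chi_square"
  } else {
    p <- stats::fisher.test(tab)$p.value
    test_used <- "fisher_exact"
  }
  structure(list(p_value = min(p, 1), test_used = test_used,
                 odds_ratio = if (or_undefined) NA_real_ else or,
                 or_undefined = or_undefined, table = tab),
            class = "rv_enrichment")
}

#' @export
print.rv_enrichment <- function(x, ...) {
  cat(sprintf("Allele-count enrichment: p = %.4g (%s), OR = %s\n",
              x$p_value, x$test_used,
              if (x$or_undefined) "undefined" else sprintf("%.3g", x$odds_ratio)))
  invisible(x)
}

#' Enrichment tests for every row of a variant table
#'
#' For each variant with both a cohort MAF and a control MAF, reconstructs
#' allele counts under the supplied total allele numbers (see
#' [maf_to_counts()]) and runs [allele_count_test()]. Printed MAFs are
#' treated as given; the assumed allele numbers are recorded in the output.
#'
#' @param variants Variant table with `cohort_maf_pct` and `control_maf_pct`
#'   columns (percent).
#' @param cohort_an Total allele number of the cohort (e.g. 2 x individuals
#'   screened).
#' @param control_an Assumed total allele number of the control population.
#' @return The table with `enrich_p`, `enrich_test`, `enrich_or`,
#'   `cohort_an`, `control_an` columns appended (NA where a MAF is missing).
#' @export
enrich_variants <- function(variants, cohort_an, control_an) {
  req <- c("cohort_maf_pct", "control_maf_pct")
  if (!all(req %in% names(variants)))
    stop("variant table lacks column(s): ",
         paste(setdiff(req, names(variants)), collapse = ", "))
  n <- nrow(variants)
  p <- or <- rep(NA_real_, n)
  test <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cm <- variants$cohort_maf_pct[i]
    gm <- variants$control_maf_pct[i]
    if (is.na(cm) || is.na(gm)) next
    res <- allele_count_test(maf_to_counts(cm, cohort_an),
                             maf_to_counts(gm, control_an))
    p[i] <- res$p_value
    or[i] <- res$odds_ratio
    test[i] <- res$test_used
  }
  variants$enrich_p <- p
  variants$enrich_test <- test
  variants$enrich_or <- or
  variants$cohort_an <- cohort_an
  variants$control_an <- control_an
  variants
}
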