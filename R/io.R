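#' Read an annotated variant table
#'
#' Reads a tab-separated variant table (the dialect of the packaged PAM
#' table). Required columns: `hgvs_c` and `consequence`. Percent and count
#' columns are parsed with a locale-independent decimal point; unknown
#' columns are preserved untouched. Each `hgvs_c` is parsed (see
#' [parse_cdna_position()]); a row whose HGVS does not parse raises an error
#' naming the line.
#'
#' @param path TSV file path.
#' @return A `data.frame` with the file's columns plus `anchor_bp`,
#'   `intron_offset`, `utr3` extracted from `hgvs_c`.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), dec = ".")
  if (nrow(df) == 0L) stop("variant table is empty: ", path)
  for (req in c("hgvs_c", "consequence"))
    if (!req %in% names(df))
      stop("variant table lacks required column '", req, "'")
  pos <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    pos[[i]] <- tryCatch(parse_cdna_position(df$hgvs_c[i]),
                         error = function(e)
                           stop("line ", i + 1L, ": ", conditionMessage(e),
                                call. = FALSE))
  }
  pos <- do.call(rbind, pos)
  df$anchor_bp <- pos$anchor_bp
  df$intron_offset <- pos$intron_offset
  df$utr3 <- pos$utr3
  df
}

#' @rdname read_variant_table
#' @param variants Variant `data.frame`.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' The packaged prioritized-variant table
#'
#' The 16 prioritized coding variants and 7 regulatory variants of the PAM
#' pituitary-adenoma screen, with their published annotations: HGVS c. and
#' p. descriptions, gene/protein location labels, cohort and population
#' MAFs, homozygote counts, in-silico verdict counts from a 19-tool panel,
#' splice/regulatory effect flags, and published-functional-evidence flags.
#'
#' @return A `data.frame` of 23 variants (see [read_variant_table()]).
#' @export
pam_variant_table <- function() {
  read_variant_table(system.file("extdata", "pam_variants.tsv",
                                 package = "rvgene", mustWork = TRUE))
}

#' Read and write dosage matrices as TSV
#'
#' Samples in rows (first column `sample_id`), variants in columns headed by
#' their identifiers; cells are 0/1/2 or NA.
#'
#' @param path TSV path.
#' @return `read_dosage_tsv()` returns a [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "sample_id")
    stop("dosage TSV must start with a 'sample_id' column")
  genotype_matrix(as.matrix(df[, -1L, drop = FALSE]),
                  variant_ids = names(df)[-1L],
                  sample_ids = as.character(df$sample_id))
}

#' @rdname read_dosage_tsv
#' @param genotypes A [genotype_matrix()].
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  df <- data.frame(sample_id = genotypes$sample_ids,
                   genotypes$dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Reads a VCF (via the vcfR package), keeps bi-allelic SNV records with a
#' GT field, and converts genotypes to minor-allele dosages. Multi-allelic
#' records are rejected with a message naming them.
#'
#' @param path VCF path (plain or bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record(s) not supported: ",
         paste(fix[multi, "ID"], collapse = ", "))
  snv <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  if (!all(snv))
    stop("non-SNV record(s) not supported: ",
         paste(fix[!snv, "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1L, 2L), function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1L]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  })
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  genotype_matrix(t(dose), variant_ids = ids, sample_ids = colnames(gt))
}

#' Write genotypes as a minimal VCF 4.2
#'
#' GT-only bi-allelic records on a placeholder contig; positions default to
#' the variant index. Intended for round-tripping simulated genotypes
#' through standard tooling.
#'
#' @param genotypes A [genotype_matrix()]; missing dosages become `./.`.
#' @param path Output path (plain text).
#' @param chrom Contig name.
#' @param positions Optional integer positions (default `1:m`).
#' @export
write_genotypes_vcf <- function(genotypes, path, chrom = "chr1",
                                positions = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  D <- genotypes$dosages
  m <- ncol(D)
  positions <- positions %||% seq_len(m)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", chrom, ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypes$sample_ids),
                     collapse = "\t")), con)
  for (j in seq_len(m)) {
    g <- D[, j]
    cells <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(chrom, positions[j], genotypes$variant_ids[j], "A",
                       "G", ".", "PASS", ".", "GT", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' TSV keyed by `sample_id` with a binary `phenotype` column; any further
#' numeric columns are covariates.
#'
#' @param path TSV path.
#' @param sample_ids Optional sample ordering to align to (error on
#'   mismatch).
#' @return List with `phenotypes` (0/1 vector), `covariates` (matrix or
#'   NULL), `sample_ids`.
#' @export
read_phenotypes <- function(path, sample_ids = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (req in c("sample_id", "phenotype"))
    if (!req %in% names(df)) stop("phenotype table lacks column '", req, "'")
  if (!is.null(sample_ids)) {
    idx <- match(sample_ids, df$sample_id)
    if (anyNA(idx))
      stop("phenotype table is missing sample(s): ",
           paste(sample_ids[is.na(idx)], collapse = ", "))
    df <- df[idx, , drop = FALSE]
  }
  cov_cols <- setdiff(names(df), c("sample_id", "phenotype"))
  covariates <- if (length(cov_cols)) {
    cv <- as.matrix(df[, cov_cols, drop = FALSE])
    rownames(cv) <- NULL
    cv
  }
  list(phenotypes = as.integer(df$phenotype),
       covariates = covariates,
       sample_ids = as.character(df$sample_id))
}
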