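#' Construct a single-transcript gene model
#'
#' A gene model holds the coding-sequence length of one transcript and an
#' ordered set of non-overlapping protein-domain intervals. It is the frame
#' of reference for mapping HGVS c. positions to residues and domains and for
#' the spatial-clustering statistics.
#'
#' @param gene Gene symbol.
#' @param transcript Transcript identifier the c. coordinates refer to.
#' @param cds_length_bp CDS length in base pairs; must equal
#'   `3 * protein_length_aa` (stop codon excluded from the protein length is
#'   not assumed: the model simply requires consistency).
#' @param protein_length_aa Protein length in residues.
#' @param domains `data.frame` with columns `name`, `start_aa`, `end_aa`
#'   (1-based closed residue intervals). Intervals must be sorted,
#'   non-overlapping, and lie within `[1, protein_length_aa]`; gaps between
#'   domains are allowed.
#' @return An object of class `gene_model`.
#' @seealso [read_gene_model()], [pam_gene_model()], [assign_domain()]
#' @export
gene_model <- function(gene, transcript, cds_length_bp, protein_length_aa,
                       domains) {
  stopifnot(is.character(gene), length(gene) == 1L,
            is.character(transcript), length(transcript) == 1L)
  cds_length_bp <- as.integer(cds_length_bp)
  protein_length_aa <- as.integer(protein_length_aa)
  if (cds_length_bp <= 0L || protein_length_aa <= 0L)
    stop("cds_length_bp and protein_length_aa must be positive")
  if (cds_length_bp != 3L * protein_length_aa)
    stop("cds_length_bp (", cds_length_bp, ") must equal 3 * protein_length_aa (",
         3L * protein_length_aa, ")")
  domains <- as.data.frame(domains, stringsAsFactors = FALSE)
  req <- c("name", "start_aa", "end_aa")
  if (!all(req %in% names(domains)))
    stop("domains must have columns: ", paste(req, collapse = ", "))
  domains$start_aa <- as.integer(domains$start_aa)
  domains$end_aa <- as.integer(domains$end_aa)
  if (any(domains$start_aa > domains$end_aa))
    stop("domain start_aa must be <= end_aa")
  if (any(domains$start_aa < 1L) || any(domains$end_aa > protein_length_aa))
    stop("domains must lie within [1, protein_length_aa]")
  o <- order(domains$start_aa)
  domains <- domains[o, , drop = FALSE]
  rownames(domains) <- NULL
  if (nrow(domains) > 1L &&
      any(domains$start_aa[-1L] <= domains$end_aa[-nrow(domains)]))
    stop("domain intervals must be non-overlapping")
  structure(
    list(gene = gene, transcript = transcript,
         cds_length_bp = cds_length_bp,
         protein_length_aa = protein_length_aa,
         domains = domains),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model:", x$gene, "(", x$transcript, ")\n")
  cat("  CDS:", x$cds_length_bp, "bp; protein:", x$protein_length_aa, "aa\n")
  cat("  Domains:\n")
  for (i in seq_len(nrow(x$domains)))
    cat(sprintf("    %-12s %4d-%4d aa\n", x$domains$name[i],
                x$domains$start_aa[i], x$domains$end_aa[i]))
  invisible(x)
}

#' Read or write a gene model as JSON
#'
#' The on-disk form is
#' `{gene, transcript, cds_length_bp, protein_length_aa, domains: [{name,
#' start_aa, end_aa}]}` so that domain boundaries are editable configuration
#' rather than constants baked into code.
#'
#' @param path Path to a JSON file.
#' @return `read_gene_model()` returns a [gene_model()];
#'   `write_gene_model()` returns `path` invisibly.
#' @export
read_gene_model <- function(path) {
  x <- jsonlite::fromJSON(path)
  gene_model(gene = x$gene, transcript = x$transcript,
             cds_length_bp = x$cds_length_bp,
             protein_length_aa = x$protein_length_aa,
             domains = x$domains)
}

#' @rdname read_gene_model
#' @param model A [gene_model()].
#' @export
write_gene_model <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  jsonlite::write_json(
    list(gene = model$gene, transcript = model$transcript,
         cds_length_bp = model$cds_length_bp,
         protein_length_aa = model$protein_length_aa,
         domains = model$domains),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The packaged PAM gene model
#'
#' Default domain map for human PAM (NM_000919.3; CDS 2,922 bp, 974 aa):
#' N-terminus 1-36, PHMcc 37-356, linker 357-497, PALcc 498-820, C-terminus
#' 821-974. The boundaries are configuration: published domain annotations
#' for PAM differ by a few residues at the PHMcc/linker edges, so analyses
#' that depend on exact boundaries should treat this map as one defensible
#' choice, editable via [read_gene_model()].
#'
#' @return A [gene_model()].
#' @export
pam_gene_model <- function() {
  read_gene_model(system.file("extdata", "pam_gene_model.json",
                              package = "rvgene", mustWork = TRUE))
}

#' Parse an HGVS c. position
#'
#' Extracts the coordinate part of an HGVS coding-DNA description. Supported
#' position tokens: plain CDS positions (`c.1654G>A`), 5'UTR positions
#' (`c.-133T>C`, negative anchor), 3'UTR positions (`c.*1455C>T`, anchor is
#' the offset past the CDS end and `utr3` is set), and intronic offsets
#' relative to an exonic anchor (`c.2332-2A>T`). The edit token (e.g.
#' `G>A`, `del`, `dup`) is retained verbatim but not interpreted.
#'
#' @param hgvs_c Character vector of HGVS c. descriptions.
#' @return A `data.frame` of class `cdna_position` with columns `hgvs_c`,
#'   `anchor_bp` (signed; negative = 5'UTR; for 3'UTR the offset past the CDS
#'   end), `intron_offset` (0 for exonic positions), `utr3` (logical), and
#'   `edit` (uninterpreted remainder).
#' @examples
#' parse_cdna_position(c("c.1654G>A", "c.2332-2A>T", "c.-133T>C"))
#' @export
parse_cdna_position <- function(hgvs_c) {
  stopifnot(is.character(hgvs_c), length(hgvs_c) >= 1L)
  parse1 <- function(s) {
    if (!grepl("^c\\.", s)) {
      if (grepl("^p\\.", s))
        stop("protein-level description '", s,
             "' is not a c. position", call. = FALSE)
      stop("malformed HGVS c. description: '", s, "'", call. = FALSE)
    }
    body <- sub("^c\\.", "", s)
    # position token: optional '*' or '-', digits, optional +/- intron offset
    m <- regmatches(body, regexec("^(\\*?)(-?\\d+)([+-]\\d+)?(.*)$", body))[[1L]]
    if (length(m) == 0L || m[3L] == "")
      stop("cannot parse position token in '", s, "'", call. = FALSE)
    utr3 <- m[2L] == "*"
    anchor <- as.integer(m[3L])
    if (anchor == 0L)
      stop("HGVS c. has no position 0 (in '", s, "')", call. = FALSE)
    if (utr3 && anchor < 0L)
      stop("malformed 3'UTR position in '", s, "'", call. = FALSE)
    offset <- if (m[4L] == "") 0L else as.integer(m[4L])
    edit <- m[5L]
    if (edit == "")
      stop("missing edit token in '", s, "'", call. = FALSE)
    list(anchor_bp = anchor, intron_offset = offset, utr3 = utr3, edit = edit)
  }
  parts <- lapply(hgvs_c, parse1)
  out <- data.frame(
    hgvs_c = hgvs_c,
    anchor_bp = vapply(parts, `[[`, integer(1), "anchor_bp"),
    intron_offset = vapply(parts, `[[`, integer(1), "intron_offset"),
    utr3 = vapply(parts, `[[`, logical(1), "utr3"),
    edit = vapply(parts, `[[`, character(1), "edit"),
    stringsAsFactors = FALSE)
  class(out) <- c("cdna_position", "data.frame")
  out
}

#' Map CDS positions to protein residues
#'
#' Codon `n` covers CDS bases `3n-2 .. 3n`, so the residue is
#' `ceiling(anchor / 3)`. Intronic positions are projected to their exonic
#' anchor base (e.g. `c.2332-2` maps through base 2332): position-based gene
#' statistics here are normalized to CDS length, and splice variants are
#' analyzed at the exon boundary they disrupt.
#'
#' @param pos A `cdna_position` (from [parse_cdna_position()]) or an integer
#'   vector of CDS anchor positions.
#' @param model A [gene_model()].
#' @return Integer vector of residue numbers in `[1, protein_length_aa]`.
#' @examples
#' m <- pam_gene_model()
#' cdna_to_protein(parse_cdna_position("c.1654G>A"), m)  # residue 552
#' @export
cdna_to_protein <- function(pos, model) {
  stopifnot(inherits(model, "gene_model"))
  if (inherits(pos, "cdna_position")) {
    if (any(pos$utr3))
      stop("3'UTR positions have no protein residue: ",
           paste(pos$hgvs_c[pos$utr3], collapse = ", "))
    anchor <- pos$anchor_bp
  } else {
    anchor <- as.integer(pos)
  }
  bad <- anchor < 1L | anchor > model$cds_length_bp
  if (any(bad))
    stop("position(s) outside the CDS [1, ", model$cds_length_bp, "]: ",
         paste(anchor[bad], collapse = ", "))
  as.integer(ceiling(anchor / 3))
}

#' Assign protein residues to named domains
#'
#' Total function on `[1, protein_length_aa]`: residues falling in no
#' annotated interval get the sentinel label `"outside-annotated-domains"`.
#'
#' @param residue Integer vector of residue numbers.
#' @param model A [gene_model()].
#' @return Character vector of domain labels.
#' @export
assign_domain <- function(residue, model) {
  stopifnot(inherits(model, "gene_model"))
  residue <- as.integer(residue)
  if (any(residue < 1L) || any(residue > model$protein_length_aa))
    stop("residues must lie in [1, ", model$protein_length_aa, "]")
  d <- model$domains
  out <- rep("outside-annotated-domains", length(residue))
  for (i in seq_len(nrow(d))) {
    hit <- residue >= d$start_aa[i] & residue <= d$end_aa[i]
    out[hit] <- d$name[i]
  }
  out
}

#' Domain intervals in CDS coordinates
#'
#' Expands each residue interval `[start_aa, end_aa]` to the codon span
#' `[3*start_aa - 2, 3*end_aa]` in CDS base pairs; a variant belongs to a
#' domain iff its anchor base falls inside this span.
#'
#' @param model A [gene_model()].
#' @return `data.frame` with columns `name`, `start_bp`, `end_bp`.
#' @export
domain_cds_intervals <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  d <- model$domains
  data.frame(name = d$name,
             start_bp = 3L * d$start_aa - 2L,
             end_bp = 3L * d$end_aa,
             stringsAsFactors = FALSE)
}
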