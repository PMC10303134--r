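#' Severity-weight scheme for variant consequences
#'
#' Integer weights expressing how damaging a variant consequence is expected
#' to be, used to weight variants in the association test. The default
#' ledger: 5 for UTR, synonymous and splice-region variants; 10 for
#' protein-altering; 20 for start-lost, stop-lost and in-frame indels;
#' missense variants get 20 plus a PolyPhen-2 increment (+20 probably
#' damaging, +10 possibly damaging, +5 unknown, +0 benign) plus a SIFT
#' increment (+20 deleterious, +0 tolerated or missing); 75 for frameshift,
#' nonsense and canonical splice acceptor/donor variants; 100 for transcript
#' ablation, the maximum of the scheme. SIFT low-confidence calls inherit
#' the increment of their confident counterpart.
#'
#' @param base_weights Named non-negative integer vector/list mapping
#'   non-missense consequence classes to weights.
#' @param missense_base Base weight for missense variants.
#' @param polyphen_increments Named increments for PolyPhen-2 classes.
#' @param sift_increments Named increments for SIFT classes.
#' @return An object of class `weight_scheme`.
#' @export
weight_scheme <- function(base_weights, missense_base,
                          polyphen_increments, sift_increments) {
  bw <- unlist(base_weights)
  pp <- unlist(polyphen_increments)
  sf <- unlist(sift_increments)
  mb <- as.integer(missense_base)
  if (any(c(bw, pp, sf, mb) < 0)) stop("weights must be non-negative")
  if (!"transcript_ablation" %in% names(bw))
    stop("base_weights must include transcript_ablation")
  max_missense <- mb + max(pp) + max(sf)
  if (bw[["transcript_ablation"]] < max(bw, max_missense))
    stop("transcript_ablation must carry the maximum weight of the scheme")
  structure(list(base_weights = as.integer(bw) |> stats::setNames(names(bw)),
                 missense_base = mb,
                 polyphen_increments = as.integer(pp) |> stats::setNames(names(pp)),
                 sift_increments = as.integer(sf) |> stats::setNames(names(sf))),
            class = "weight_scheme")
}

#' @rdname weight_scheme
#' @export
default_weight_scheme <- function() {
  read_weight_scheme(system.file("extdata", "default_weight_scheme.json",
                                 package = "rvgene", mustWork = TRUE))
}

#' @rdname weight_scheme
#' @param path JSON file path.
#' @export
read_weight_scheme <- function(path) {
  x <- jsonlite::fromJSON(path)
  weight_scheme(x$base_weights, x$missense_base,
                x$polyphen_increments, x$sift_increments)
}

#' @rdname weight_scheme
#' @param scheme A `weight_scheme`.
#' @export
write_weight_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "weight_scheme"))
  jsonlite::write_json(
    list(base_weights = as.list(scheme$base_weights),
         missense_base = scheme$missense_base,
         polyphen_increments = as.list(scheme$polyphen_increments),
         sift_increments = as.list(scheme$sift_increments)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Severity-weight scheme\n")
  bw <- sort(x$base_weights)
  for (nm in names(bw)) cat(sprintf("  %-20s %d\n", nm, bw[[nm]]))
  cat(sprintf("  %-20s %d + PolyPhen {%s} + SIFT {%s}\n", "missense",
              x$missense_base,
              paste(names(x$polyphen_increments), x$polyphen_increments,
                    sep = ":", collapse = ", "),
              paste(names(x$sift_increments), x$sift_increments,
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Assign a severity weight to a variant consequence
#'
#' Pure lookup in the scheme: non-missense consequences take their base
#' weight; missense variants take `missense_base` plus the PolyPhen-2 and
#' SIFT increments. A missing PolyPhen class is treated as `"unknown"` (the
#' ledger's +5) and a missing SIFT class as `"missing"` (+0).
#'
#' @param consequence Character vector of consequence classes.
#' @param polyphen_class,sift_class Optional character vectors (recycled
#'   `NA`s allowed); only consulted for missense consequences.
#' @param scheme A [weight_scheme()].
#' @return Integer vector of weights.
#' @examples
#' assign_weight("frameshift")                       # 75
#' assign_weight("missense", "probably_damaging", "deleterious")  # 60
#' @export
assign_weight <- function(consequence, polyphen_class = NA_character_,
                          sift_class = NA_character_,
                          scheme = default_weight_scheme()) {
  stopifnot(inherits(scheme, "weight_scheme"))
  n <- length(consequence)
  polyphen_class <- rep_len(as.character(polyphen_class), n)
  sift_class <- rep_len(as.character(sift_class), n)
  known <- c(names(scheme$base_weights), "missense")
  bad <- !consequence %in% known
  if (any(bad))
    stop("unknown consequence label(s): ",
         paste(unique(consequence[bad]), collapse = ", "),
         "; allowed: ", paste(sort(known), collapse = ", "))
  out <- integer(n)
  mis <- consequence == "missense"
  out[!mis] <- scheme$base_weights[consequence[!mis]]
  if (any(mis)) {
    pp <- polyphen_class[mis]
    pp[is.na(pp)] <- "unknown"
    sf <- sift_class[mis]
    sf[is.na(sf)] <- "missing"
    badp <- !pp %in% names(scheme$polyphen_increments)
    bads <- !sf %in% names(scheme$sift_increments)
    if (any(badp))
      stop("unknown PolyPhen class(es): ", paste(unique(pp[badp]), collapse = ", "),
           "; allowed: ", paste(names(scheme$polyphen_increments), collapse = ", "))
    if (any(bads))
      stop("unknown SIFT class(es): ", paste(unique(sf[bads]), collapse = ", "),
           "; allowed: ", paste(names(scheme$sift_increments), collapse = ", "))
    out[mis] <- scheme$missense_base +
      scheme$polyphen_increments[pp] + scheme$sift_increments[sf]
  }
  unname(out)
}

#' Attach severity weights to a variant table
#'
#' Adds a `weight` column computed by [assign_weight()] from the table's
#' `consequence` column and, where present, `polyphen_class` and
#' `sift_class` columns.
#'
#' @param variants A variant `data.frame` (see [read_variant_table()]).
#' @param scheme A [weight_scheme()].
#' @return The table with a `weight` column appended.
#' @export
weigh_variants <- function(variants, scheme = default_weight_scheme()) {
  if (!"consequence" %in% names(variants))
    stop("variant table lacks a 'consequence' column")
  variants$weight <- assign_weight(
    variants$consequence,
    variants$polyphen_class %||% NA_character_,
    variants$sift_class %||% NA_character_,
    scheme)
  variants
}
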