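# expression_weighting: size factors, count normalization, expression-weighted
# per-tissue codon usage, max-normalization.

#' Median-of-ratios size factors
#'
#' For each column j, the size factor is the median over reference rows of
#' `counts[i, j] / ref[i]`, where `ref[i]` is the geometric mean of row i
#' across columns. By default only rows with no zero count serve as the
#' reference; `max_zero_rows` relaxes this to rows with at most that many
#' zeros, with the geometric mean then taken over the positive entries
#' (pseudo-reference fallback for sparse matrices).
#'
#' @param m Non-negative count matrix with at least two columns.
#' @param max_zero_rows Maximum zeros tolerated in a reference row (default 0).
#' @return Numeric vector of positive size factors, one per column.
#' @export
median_of_ratios_size_factors <- function(m, max_zero_rows = 0L) {
  stopifnot(is.matrix(m))
  if (ncol(m) < 2L) stop("need at least 2 columns", call. = FALSE)
  nz <- rowSums(m == 0)
  keep <- nz <= max_zero_rows
  if (!any(keep)) {
    stop("no row with at most ", max_zero_rows, " zero counts; increase ",
         "max_zero_rows to enable the pseudo-reference fallback",
         call. = FALSE)
  }
  sub <- m[keep, , drop = FALSE]
  logm <- log(sub)
  logm[!is.finite(logm)] <- NA            # zeros under the fallback
  ref <- exp(rowMeans(logm, na.rm = TRUE))
  sf <- apply(sub / ref, 2L, stats::median)
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("degenerate size factor; counts too sparse", call. = FALSE)
  }
  stats::setNames(sf, colnames(m))
}

#' Attach median-of-ratios size factors to a count matrix
#'
#' @inheritParams median_of_ratios_size_factors
#' @return `m` with a `size_factors` attribute set.
#' @export
estimate_size_factors <- function(m, max_zero_rows = 0L) {
  attr(m, "size_factors") <- median_of_ratios_size_factors(m, max_zero_rows)
  m
}

#' Normalize a count matrix by its size factors
#'
#' Divides each column by its size factor and resets the stored size factors
#' to 1, so the operation is idempotent. Counts the paper-style pipelines
#' consume are often already normalized; pass `pre_normalized = TRUE` to
#' accept such a matrix unchanged.
#'
#' @param m Count matrix.
#' @param size_factors Per-column positive factors; defaults to the matrix's
#'   `size_factors` attribute.
#' @param pre_normalized If `TRUE`, skip normalization.
#' @return Normalized matrix with `size_factors` attribute all 1.
#' @export
normalize_counts <- function(m, size_factors = attr(m, "size_factors"),
                             pre_normalized = FALSE) {
  stopifnot(is.matrix(m))
  if (pre_normalized) {
    attr(m, "size_factors") <- stats::setNames(rep(1, ncol(m)), colnames(m))
    return(m)
  }
  if (is.null(size_factors)) {
    stop("size factors unset: call estimate_size_factors() first or pass ",
         "pre_normalized = TRUE", call. = FALSE)
  }
  stopifnot(length(size_factors) == ncol(m), all(size_factors > 0))
  out <- sweep(m, 2L, size_factors, "/")
  attr(out, "size_factors") <- stats::setNames(rep(1, ncol(m)), colnames(m))
  out
}

#' Expression-weighted codon usage for one tissue
#'
#' Multiplies each gene's normalized count in `tissue` by that gene's CDS
#' codon frequency and sums over genes: the tissue's codon demand. Matrix rows
#' may be keyed by gene or transcript id (an optional `id_map` translates
#' other schemes); rows that resolve to no catalog entry are skipped with a
#' message, and rows resolving to the same gene are summed.
#'
#' @param catalog A one-isoform-per-gene `transcript_catalog`.
#' @param m Normalized count matrix (rows = genes/transcripts, columns =
#'   tissues).
#' @param tissue Column name to use.
#' @param gene_list Optional character vector restricting the sum to these
#'   gene ids (e.g. a differential-expression list).
#' @param id_map Optional data frame with columns `transcript_id`, `gene_id`
#'   used to translate row ids before matching.
#' @param lenient Passed to [count_elongator_codons()].
#' @return Object of class `tissue_usage`: list with `tissue`, `raw_usage`
#'   (`WEIGHTED_USAGE` profile), `scaled_usage` (`NULL` until
#'   [max_normalize_usage()]), `n_genes_used`, `n_skipped`.
#' @export
weighted_codon_usage <- function(catalog, m, tissue, gene_list = NULL,
                                 id_map = NULL, lenient = FALSE) {
  stopifnot(is.matrix(m))
  if (!tissue %in% colnames(m)) {
    stop("tissue column not found: ", tissue, call. = FALSE)
  }
  ids <- rownames(m)
  if (is.null(ids)) stop("count matrix has no row ids", call. = FALSE)
  if (!is.null(id_map)) {
    hit <- match(ids, id_map$transcript_id)
    ids <- ifelse(is.na(hit), ids, id_map$gene_id[hit])
  }
  gene <- catalog$gene_id[match(ids, catalog$gene_id)]
  via_tr <- is.na(gene)
  gene[via_tr] <- catalog$gene_id[match(ids[via_tr], catalog$transcript_id)]
  matched <- !is.na(gene)
  if (!is.null(gene_list)) matched <- matched & gene %in% gene_list
  n_skipped <- sum(!matched & (is.null(gene_list) | is.na(gene)))
  if (n_skipped > 0L) {
    message(n_skipped, " count row(s) not resolvable to a catalog gene; ",
            "skipped")
  }
  if (!any(matched)) stop("zero genes matched between counts and catalog",
                          call. = FALSE)
  counts <- m[matched, tissue]
  genes <- gene[matched]
  # collapse transcript-level rows mapping to one gene
  counts <- tapply(counts, factor(genes, levels = unique(genes)), sum)
  genes <- names(counts)
  rows <- match(genes, catalog$gene_id)
  freq <- t(vapply(catalog$seq[rows], function(s) {
    as.numeric(codon_frequency(count_elongator_codons(s, lenient)))
  }, numeric(64L)))
  raw <- as.numeric(counts %*% freq)
  structure(list(
    tissue = tissue,
    raw_usage = codon_profile(raw, kind = "WEIGHTED_USAGE"),
    scaled_usage = NULL,
    n_genes_used = length(genes),
    n_skipped = n_skipped
  ), class = "tissue_usage")
}

#' @export
print.tissue_usage <- function(x, ...) {
  cat(sprintf("<tissue_usage> %s: %d genes used, %d skipped, %s\n",
              x$tissue, x$n_genes_used, x$n_skipped,
              if (is.null(x$scaled_usage)) "raw" else "max-normalized"))
  invisible(x)
}

#' Max-normalize a usage profile to the unit interval
#'
#' Divides the summed usage of each codon by the maximum across all 64
#' codons, so the most-used codon maps to exactly 1. This makes usage
#' comparable across sequencing depths and is the scale on which the
#' tissue/genome bias ratio is taken.
#'
#' @param x A `tissue_usage` (fills its `scaled_usage` slot) or a
#'   `codon_profile`.
#' @return Same class as the input; for a profile, kind `MAX_NORMALIZED`.
#' @export
max_normalize_usage <- function(x) {
  if (inherits(x, "tissue_usage")) {
    x$scaled_usage <- max_normalize_usage(x$raw_usage)
    return(x)
  }
  stopifnot(inherits(x, "codon_profile"))
  v <- unclass(x)
  mx <- max(v)
  if (mx <= 0) {
    warning("all-zero usage profile; scaled profile is all zero")
    return(codon_profile(v * 0, kind = "MAX_NORMALIZED"))
  }
  codon_profile(v / mx, kind = "MAX_NORMALIZED")
}
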