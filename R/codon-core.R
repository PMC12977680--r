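# codon_core: elongator-codon counting, frequencies, enrichment ranking,
# genome baseline.

#' Construct a codon count vector
#'
#' @param counts Integer vector of length 64 in the package codon order
#'   (see [codons()]), or a named vector over a subset of codons.
#' @param total_elongator Total elongator codons; defaults to the sum over
#'   sense codons.
#' @return Object of class `codon_counts`: a named length-64 integer vector
#'   with a `total_elongator` attribute.
#' @export
codon_counts <- function(counts, total_elongator = NULL) {
  full <- stats::setNames(integer(64L), .CODONS)
  if (!is.null(names(counts))) {
    nm <- .check_codon_set(names(counts))
    full[nm] <- as.integer(counts[nm])
  } else {
    stopifnot(length(counts) == 64L)
    full[] <- as.integer(counts)
  }
  if (any(full < 0L)) stop("negative codon count", call. = FALSE)
  if (is.null(total_elongator)) total_elongator <- sum(full[.SENSE_IDX])
  structure(full, total_elongator = as.integer(total_elongator),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  nz <- x[x > 0]
  cat(sprintf("<codon_counts> total_elongator = %d, %d codons observed\n",
              attr(x, "total_elongator"), length(nz)))
  print(utils::head(sort(unclass(nz), decreasing = TRUE), 10L))
  invisible(x)
}

#' Total elongator codons in a count vector
#' @param x A `codon_counts` object.
#' @return Integer scalar.
#' @export
total_elongator <- function(x) attr(x, "total_elongator")

#' Count elongator codons in one CDS
#'
#' Counts in-frame codons from the second codon onwards: the initiator codon
#' is excluded because it is decoded by the initiator tRNA, not by elongating
#' tRNAs, and the terminal codon is excluded if (and only if) it is a stop
#' triplet. Codons containing a non-ACGT character are skipped and excluded
#' from the elongator total. Internal stop triplets (possible only on
#' unvalidated input) are recorded in their stop slots but never counted as
#' elongator codons, so `sum(counts[sense]) == total_elongator` always holds.
#'
#' @param seq CDS string, or a single-row `transcript_catalog`.
#' @param lenient If `FALSE` (default), a length that is not a multiple of 3,
#'   or a CDS with no elongator codon, is an error. If `TRUE`, the sequence is
#'   truncated to frame and degenerate CDS yield a zero vector.
#' @return A `codon_counts` object.
#' @export
#' @examples
#' count_elongator_codons("ATGACTTAA")  # one elongator codon: ACT
count_elongator_codons <- function(seq, lenient = FALSE) {
  if (inherits(seq, "transcript_catalog")) {
    stopifnot(nrow(seq) == 1L)
    seq <- seq$seq
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- .clean_seq(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    if (!lenient) {
      stop("CDS length ", n, " is not a multiple of 3 (use lenient = TRUE ",
           "to truncate to frame)", call. = FALSE)
    }
    n <- n - n %% 3L
  }
  n3 <- n %/% 3L
  if (n3 < 2L) {
    if (!lenient) stop("CDS has no elongator codons", call. = FALSE)
    return(codon_counts(integer(64L), 0L))
  }
  starts <- 3L * seq.int(2L, n3) - 2L      # codons 2..n3
  cods <- substring(seq, starts, starts + 2L)
  k <- length(cods)
  if (cods[k] %in% .STOP_CODONS) cods <- cods[-k]
  idx <- match(cods, .CODONS)              # NA for ambiguous codons
  tab <- tabulate(idx[!is.na(idx)], nbins = 64L)
  codon_counts(tab, total_elongator = sum(tab[.SENSE_IDX]))
}

# Count matrix for a whole catalog: genes/transcripts x 64.
.catalog_count_matrix <- function(catalog, lenient = FALSE) {
  m <- t(vapply(catalog$seq,
                function(s) as.integer(count_elongator_codons(s, lenient)),
                integer(64L)))
  dimnames(m) <- list(catalog$transcript_id, .CODONS)
  m
}

#' Construct a codon usage profile
#'
#' @param values Numeric vector of length 64 (or named over a subset), all
#'   non-negative.
#' @param kind One of `"FREQUENCY"`, `"WEIGHTED_USAGE"`, `"MAX_NORMALIZED"`.
#' @return Object of class `codon_profile`: named length-64 numeric vector
#'   with a `kind` attribute.
#' @export
codon_profile <- function(values,
                          kind = c("FREQUENCY", "WEIGHTED_USAGE",
                                   "MAX_NORMALIZED")) {
  kind <- match.arg(kind)
  full <- stats::setNames(numeric(64L), .CODONS)
  if (!is.null(names(values))) {
    nm <- .check_codon_set(names(values))
    full[nm] <- as.numeric(values[nm])
  } else {
    stopifnot(length(values) == 64L)
    full[] <- as.numeric(values)
  }
  if (any(full < 0)) stop("negative usage value", call. = FALSE)
  structure(full, kind = kind, class = "codon_profile")
}

#' @export
print.codon_profile <- function(x, ...) {
  cat(sprintf("<codon_profile> kind = %s\n", attr(x, "kind")))
  print(utils::head(sort(unclass(x), decreasing = TRUE), 10L))
  invisible(x)
}

#' Per-CDS codon frequency
#'
#' Divides each codon's count by the total number of elongator codons in the
#' CDS, giving a frequency profile that sums to 1 over the sense codons.
#'
#' @param counts A `codon_counts` object with `total_elongator > 0`.
#' @return A `codon_profile` of kind `FREQUENCY`.
#' @export
codon_frequency <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  tot <- attr(counts, "total_elongator")
  if (tot == 0L) stop("no elongator codons: frequency undefined", call. = FALSE)
  codon_profile(unclass(counts) / tot, kind = "FREQUENCY")
}

#' Summed frequency of a codon set
#'
#' The fraction of elongator codons falling in `codon_set` — e.g. the combined
#' ACT + ACC share of a CDS.
#'
#' @param x A `codon_counts` or a `codon_profile` of kind `FREQUENCY`.
#' @param codon_set Non-empty character vector of codons.
#' @return Numeric scalar in `[0, 1]`.
#' @export
codon_set_fraction <- function(x, codon_set = c("ACT", "ACC")) {
  codon_set <- .check_codon_set(codon_set)
  if (inherits(x, "codon_counts")) x <- codon_frequency(x)
  stopifnot(inherits(x, "codon_profile"))
  if (attr(x, "kind") != "FREQUENCY") {
    stop("codon_set_fraction needs a FREQUENCY profile", call. = FALSE)
  }
  sum(unclass(x)[codon_set])
}

#' Rank genes by enrichment of a codon set
#'
#' For each CDS in a one-isoform-per-gene catalog, counts elongator codons,
#' computes the summed fraction of `codon_set`, and returns genes sorted by
#' that fraction (descending), then by elongator total (descending), then by
#' gene_id. Short CDS make fractions unstable, so genes with fewer than
#' `min_elongator` elongator codons are dropped.
#'
#' @param catalog A non-empty `transcript_catalog`, one isoform per gene.
#' @param codon_set Codons of interest (default the ACT/ACC threonine pair).
#' @param min_elongator Minimum elongator codons for a gene to be ranked.
#' @param lenient Passed to [count_elongator_codons()].
#' @return Data frame with columns `gene_id`, `transcript_id`,
#'   `total_elongator`, `set_count`, `set_fraction`.
#' @export
rank_by_codon_enrichment <- function(catalog, codon_set = c("ACT", "ACC"),
                                     min_elongator = 50L, lenient = FALSE) {
  if (nrow(catalog) == 0L) stop("empty catalog", call. = FALSE)
  codon_set <- .check_codon_set(codon_set)
  m <- .catalog_count_matrix(catalog, lenient = lenient)
  tot <- rowSums(m[, .SENSE_CODONS, drop = FALSE])
  setc <- rowSums(m[, codon_set, drop = FALSE])
  keep <- tot >= min_elongator
  out <- data.frame(
    gene_id = catalog$gene_id[keep],
    transcript_id = catalog$transcript_id[keep],
    total_elongator = as.integer(tot[keep]),
    set_count = as.integer(setc[keep]),
    set_fraction = ifelse(tot[keep] > 0, setc[keep] / tot[keep], 0),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$set_fraction, -out$total_elongator, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Genome-wide aggregate codon usage
#'
#' Sums elongator-codon counts over every CDS in the catalog and converts the
#' total to a frequency profile: the sequence-level genome baseline against
#' which tissue usage is compared.
#'
#' @param catalog A non-empty `transcript_catalog`, one isoform per gene.
#' @param lenient Passed to [count_elongator_codons()].
#' @return List with `counts` (a `codon_counts`) and `profile` (a `FREQUENCY`
#'   `codon_profile`).
#' @export
aggregate_genome_usage <- function(catalog, lenient = FALSE) {
  if (nrow(catalog) == 0L) stop("empty catalog", call. = FALSE)
  m <- .catalog_count_matrix(catalog, lenient = lenient)
  total <- colSums(m)
  cc <- codon_counts(as.integer(total))
  if (attr(cc, "total_elongator") == 0L) {
    stop("no elongator codons in catalog", call. = FALSE)
  }
  list(counts = cc, profile = codon_frequency(cc))
}
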