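# bias_analysis: tissue-versus-genome per-codon usage ratio and the report
# across tissues.

#' Tissue/genome codon usage bias ratio
#'
#' Per-codon ratio of tissue usage to genome usage. In the default
#' `"scaled"` mode both vectors are compared on the max-normalized 0-1
#' scale, which makes the ratio independent of sequencing depth; inputs not
#' yet max-normalized are scaled internally. `"frequency"` mode compares the
#' tissue's raw weighted usage renormalized to sum 1 over sense codons
#' against the genome frequency profile (sensitivity analysis). Codons with
#' zero genome usage have no defined ratio and are reported separately.
#'
#' @param tissue A `tissue_usage` or a `codon_profile`.
#' @param genome A `codon_profile` (genome baseline, e.g. from
#'   [aggregate_genome_usage()]).
#' @param mode `"scaled"` (default) or `"frequency"`.
#' @return List with `ratio` (named length-64 numeric, `NA` where undefined)
#'   and `undefined` (codons with zero genome usage).
#' @export
usage_bias_ratio <- function(tissue, genome, mode = c("scaled", "frequency")) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome, "codon_profile"))
  g <- unclass(genome)
  t_vec <- .tissue_vector(tissue, mode)
  if (mode == "scaled") {
    if (max(g) <= 0) stop("genome profile is all zero", call. = FALSE)
    g <- g / max(g)
  } else {
    s <- sum(g[.SENSE_IDX])
    if (s <= 0) stop("genome profile is all zero", call. = FALSE)
    g <- g / s
  }
  ratio <- rep(NA_real_, 64L)
  names(ratio) <- .CODONS
  def <- g > 0
  ratio[def] <- t_vec[def] / g[def]
  list(ratio = ratio, undefined = .CODONS[!def])
}

.tissue_vector <- function(tissue, mode) {
  if (inherits(tissue, "tissue_usage")) {
    tissue <- if (mode == "scaled" && !is.null(tissue$scaled_usage)) {
      tissue$scaled_usage
    } else {
      tissue$raw_usage
    }
  }
  stopifnot(inherits(tissue, "codon_profile"))
  v <- unclass(tissue)
  if (mode == "scaled") {
    if (max(v) > 0) v / max(v) else v
  } else {
    s <- sum(v[.SENSE_IDX])
    if (s > 0) v / s else v
  }
}

#' Compare several tissues against the genome baseline
#'
#' Computes one bias-ratio vector per tissue and flags tissues in which every
#' codon of `focus_set` exceeds `ratio_threshold`. The default threshold of
#' 1.1 asks for enrichment beyond what sampling noise around parity produces;
#' set it to 1 for the literal "ratio above 1" rule.
#'
#' @param usages List of `tissue_usage` objects with distinct tissue names.
#' @param genome Genome baseline `codon_profile`.
#' @param focus_set Non-empty codon set of interest (default ACT/ACC). Stop
#'   codons are not allowed in the focus set.
#' @param ratio_threshold Flag threshold on the focus-codon ratios.
#' @param mode Passed to [usage_bias_ratio()].
#' @return Object of class `bias_report`: list with `tissues`, `ratios`
#'   (64 x tissues matrix), `tissue_scaled` (64 x tissues), `genome_scaled`,
#'   `undefined_codons` (per-tissue list), `focus_set`, `focus_flags`,
#'   `ratio_threshold`.
#' @export
compare_tissues <- function(usages, genome, focus_set = c("ACT", "ACC"),
                            ratio_threshold = 1.1,
                            mode = c("scaled", "frequency")) {
  mode <- match.arg(mode)
  if (inherits(usages, "tissue_usage")) usages <- list(usages)
  if (length(usages) == 0L) stop("need at least one tissue", call. = FALSE)
  focus_set <- .check_codon_set(focus_set)
  if (any(focus_set %in% .STOP_CODONS)) {
    stop("focus_set must contain sense codons only", call. = FALSE)
  }
  tissues <- vapply(usages, function(u) u$tissue, "")
  if (anyDuplicated(tissues)) {
    stop("duplicate tissue names: ",
         paste(unique(tissues[duplicated(tissues)]), collapse = ", "),
         call. = FALSE)
  }
  rr <- lapply(usages, usage_bias_ratio, genome = genome, mode = mode)
  ratios <- vapply(rr, function(r) r$ratio, numeric(64L))
  scaled <- vapply(usages, function(u) .tissue_vector(u, mode), numeric(64L))
  dimnames(ratios) <- dimnames(scaled) <- list(.CODONS, tissues)
  flags <- apply(ratios[focus_set, , drop = FALSE], 2L, function(r) {
    all(!is.na(r)) && all(r > ratio_threshold)
  })
  g <- unclass(genome)
  g_scaled <- if (mode == "scaled") {
    g / max(g)
  } else {
    g / sum(g[.SENSE_IDX])
  }
  structure(list(
    tissues = tissues,
    ratios = ratios,
    tissue_scaled = scaled,
    genome_scaled = stats::setNames(g_scaled, .CODONS),
    undefined_codons = stats::setNames(lapply(rr, function(r) r$undefined),
                                       tissues),
    focus_set = focus_set,
    focus_flags = stats::setNames(flags, tissues),
    ratio_threshold = ratio_threshold
  ), class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("<bias_report> %d tissue(s), focus set {%s}, threshold %.3g\n",
              length(x$tissues), paste(x$focus_set, collapse = ", "),
              x$ratio_threshold))
  show <- t(x$ratios[x$focus_set, , drop = FALSE])
  show <- cbind(as.data.frame(show), flagged = x$focus_flags)
  print(round(show, 4L))
  invisible(x)
}

#' Flatten a bias report to a per-codon table
#'
#' @param x A `bias_report`.
#' @param row.names,optional,... Ignored (data.frame method signature).
#' @return Data frame with one row per codon: `codon`, `amino_acid`,
#'   `genome_scaled`, then `<tissue>_scaled` and `<tissue>_ratio` per tissue,
#'   and `in_focus_set`.
#' @export
as.data.frame.bias_report <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  out <- data.frame(
    codon = .CODONS,
    amino_acid = .codon_aa(),
    genome_scaled = unname(x$genome_scaled),
    stringsAsFactors = FALSE
  )
  for (tt in x$tissues) {
    out[[paste0(tt, "_scaled")]] <- unname(x$tissue_scaled[, tt])
    out[[paste0(tt, "_ratio")]] <- unname(x$ratios[, tt])
  }
  out$in_focus_set <- .CODONS %in% x$focus_set
  out
}
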