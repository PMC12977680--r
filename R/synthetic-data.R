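# synthetic_data: seeded CDS catalogs with planted synonymous-codon
# preferences and negative-binomial count matrices, plus the closed-form
# expected bias the pipeline should recover.

# Average proteome amino-acid composition (fractions), used as the default
# amino-acid weighting of the synthetic preference vectors.
.AA_WEIGHTS <- c(
  A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.7, G = 7.1,
  H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9, P = 4.7, S = 6.6,
  T = 5.3, W = 1.1, Y = 2.9, V = 6.9
) / 100

#' Specify a synthetic codon-usage dataset
#'
#' Defines tissue-specific synonymous-codon preference vectors over the 61
#' sense codons and the parameters of a negative-binomial count matrix. Each
#' tissue's preference starts from a shared base — amino-acid weights times a
#' within-family tilt favouring G/C-ending codons by `gc3_bias` — and the
#' tissues named in `enrichment` get the codons of `focus_set` boosted by
#' their factor inside each affected synonymous family, renormalized within
#' the family so amino-acid composition is untouched and only *synonymous*
#' preference shifts (what a tRNA-modification effect would see).
#'
#' @param n_genes Number of genes (one transcript each).
#' @param length_range Min/max CDS length in elongator codons (uniform draw).
#' @param tissues Tissue names; genes are assigned home tissues round-robin.
#' @param enrichment Named numeric, tissue -> boost factor `f >= 1` on the
#'   focus codons (tissues absent from the vector get `f = 1`).
#' @param focus_set Codons receiving the boost (default ACT/ACC).
#' @param depth Expected count of a gene outside its home tissue.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson); variance is `mu + mu^2 / dispersion`.
#' @param de_fold Expression elevation of a gene in its home tissue.
#' @param size_factors Optional named per-tissue scale factors multiplied
#'   into the expected counts (exercises size-factor recovery).
#' @param aa_weights Named amino-acid composition (20 fractions, sum 1).
#' @param gc3_bias Within-family preference multiplier for G/C-ending codons.
#' @param seed Integer seed; fixed seed means byte-identical outputs.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 500L,
                     length_range = c(100L, 500L),
                     tissues = c("wing_disc", "fat_body", "muscle"),
                     enrichment = NULL,
                     focus_set = c("ACT", "ACC"),
                     depth = 1000,
                     dispersion = 10,
                     de_fold = 4,
                     size_factors = NULL,
                     aa_weights = NULL,
                     gc3_bias = 1.5,
                     seed = 1L) {
  stopifnot(n_genes >= 1L, length(length_range) == 2L,
            length_range[1L] >= 10L, length_range[2L] >= length_range[1L],
            length(tissues) >= 1L, !anyDuplicated(tissues),
            depth > 0, dispersion > 0, de_fold >= 1, gc3_bias > 0)
  focus_set <- .check_codon_set(focus_set)
  if (any(focus_set %in% .STOP_CODONS)) {
    stop("focus_set must be sense codons", call. = FALSE)
  }
  f <- stats::setNames(rep(1, length(tissues)), tissues)
  if (!is.null(enrichment)) {
    if (is.null(names(enrichment)) ||
        !all(names(enrichment) %in% tissues)) {
      stop("enrichment must be named by tissue", call. = FALSE)
    }
    if (any(enrichment < 1)) stop("enrichment factors must be >= 1",
                                  call. = FALSE)
    f[names(enrichment)] <- enrichment
  }
  if (is.null(aa_weights)) aa_weights <- .AA_WEIGHTS
  stopifnot(abs(sum(aa_weights) - 1) < 1e-9)
  if (!is.null(size_factors)) {
    stopifnot(length(size_factors) == length(tissues), all(size_factors > 0))
    size_factors <- stats::setNames(as.numeric(size_factors), tissues)
  }
  structure(list(
    n_genes = as.integer(n_genes),
    length_range = as.integer(length_range),
    tissues = tissues,
    enrichment = f,
    focus_set = focus_set,
    depth = depth,
    dispersion = dispersion,
    de_fold = de_fold,
    size_factors = size_factors,
    aa_weights = aa_weights,
    gc3_bias = gc3_bias,
    seed = as.integer(seed)
  ), class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(
    "<sim_spec> %d genes x %d tissues, CDS %d-%d codons, depth %g, NB size %g\n",
    x$n_genes, length(x$tissues), x$length_range[1L], x$length_range[2L],
    x$depth, x$dispersion))
  cat("enrichment:",
      paste(sprintf("%s=%g", names(x$enrichment), x$enrichment),
            collapse = ", "),
      "on", paste(x$focus_set, collapse = "/"), "\n")
  invisible(x)
}

#' Per-tissue sense-codon preference vectors
#'
#' The generative synonymous-codon probabilities implied by a [sim_spec()]:
#' a 64 x tissues matrix (stop rows are zero) whose columns each sum to 1.
#'
#' @param spec A `sim_spec`.
#' @return Numeric matrix, rownames = the 64 codons, colnames = tissues.
#' @export
tissue_preferences <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  aa <- .codon_aa()
  base <- numeric(64L)
  tilt <- ifelse(substr(.CODONS, 3L, 3L) %in% c("G", "C"), spec$gc3_bias, 1)
  for (a in names(spec$aa_weights)) {
    i <- which(aa == a)
    base[i] <- spec$aa_weights[[a]] * tilt[i] / sum(tilt[i])
  }
  base <- base / sum(base)
  pref <- matrix(base, nrow = 64L, ncol = length(spec$tissues),
                 dimnames = list(.CODONS, spec$tissues))
  fam_of_focus <- unique(aa[match(spec$focus_set, .CODONS)])
  for (tt in spec$tissues) {
    f <- spec$enrichment[[tt]]
    if (f == 1) next
    p <- pref[, tt]
    for (a in fam_of_focus) {
      i <- which(aa == a)
      fam_total <- sum(p[i])
      boost <- ifelse(.CODONS[i] %in% spec$focus_set, f, 1)
      p[i] <- p[i] * boost / sum(p[i] * boost) * fam_total
    }
    pref[, tt] <- p
  }
  pref
}

# Deterministic round-robin home-tissue assignment.
.home_tissues <- function(spec) {
  rep_len(spec$tissues, spec$n_genes)
}

#' Generate a synthetic CDS catalog with planted codon preferences
#'
#' Each gene is assigned a home tissue (round-robin) and its CDS is built as
#' `ATG` + i.i.d. sense codons drawn from the home tissue's preference vector
#' + `TAA`. The generative preferences are returned as ground truth.
#'
#' @param spec A `sim_spec`.
#' @return Object of class `codon_sim`: list with `catalog`
#'   (a `transcript_catalog`), `gene_info` (gene_id, transcript_id,
#'   home_tissue, n_codons), `preferences` (64 x tissues truth matrix) and
#'   `spec`.
#' @export
generate_catalog <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  pref <- tissue_preferences(spec)
  home <- .home_tissues(spec)
  lens <- sample(seq.int(spec$length_range[1L], spec$length_range[2L]),
                 spec$n_genes, replace = TRUE)
  seqs <- character(spec$n_genes)
  for (i in seq_len(spec$n_genes)) {
    body <- sample(.SENSE_CODONS, lens[i], replace = TRUE,
                   prob = pref[.SENSE_IDX, home[i]])
    seqs[i] <- paste0("ATG", paste(body, collapse = ""), "TAA")
  }
  gid <- sprintf("g%05d", seq_len(spec$n_genes))
  tid <- paste0(gid, ".1")
  structure(list(
    catalog = transcript_catalog(tid, gid, seqs),
    gene_info = data.frame(gene_id = gid, transcript_id = tid,
                           home_tissue = home, n_codons = lens,
                           stringsAsFactors = FALSE),
    preferences = pref,
    spec = spec
  ), class = "codon_sim")
}

#' @export
print.codon_sim <- function(x, ...) {
  cat(sprintf("<codon_sim> %d genes, tissues: %s (seed %d)\n",
              nrow(x$gene_info), paste(x$spec$tissues, collapse = ", "),
              x$spec$seed))
  invisible(x)
}

#' Generate a negative-binomial count matrix for a synthetic catalog
#'
#' Expected count of gene g in tissue t is `depth * de_fold` when t is g's
#' home tissue and `depth` otherwise, multiplied by the planted per-tissue
#' size factor when the spec defines one; counts are drawn
#' NB(mu, size = dispersion). Uses seed `spec$seed + 1` so the catalog and
#' the counts are independently reproducible.
#'
#' @param sim A `codon_sim` from [generate_catalog()].
#' @return Count matrix (genes x tissues, rownames = gene ids) with the
#'   `size_factors` attribute unset.
#' @export
generate_counts <- function(sim) {
  stopifnot(inherits(sim, "codon_sim"))
  spec <- sim$spec
  set.seed(spec$seed + 1L)
  nT <- length(spec$tissues)
  mu <- matrix(spec$depth, nrow = spec$n_genes, ncol = nT,
               dimnames = list(sim$gene_info$gene_id, spec$tissues))
  for (j in seq_len(nT)) {
    hit <- sim$gene_info$home_tissue == spec$tissues[j]
    mu[hit, j] <- spec$depth * spec$de_fold
  }
  if (!is.null(spec$size_factors)) {
    mu <- sweep(mu, 2L, spec$size_factors, "*")
  }
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = spec$dispersion),
    nrow = spec$n_genes, dimnames = dimnames(mu)
  )
  storage.mode(counts) <- "double"
  attr(counts, "size_factors") <- NULL
  counts
}

#' Ground-truth differentially expressed genes of a tissue
#'
#' The simulator's analog of a DE gene list: the genes whose home tissue is
#' `tissue` (they are `de_fold`-times elevated there).
#'
#' @param sim A `codon_sim`.
#' @param tissue Tissue name.
#' @return Character vector of gene ids.
#' @export
de_genes <- function(sim, tissue) {
  stopifnot(inherits(sim, "codon_sim"), tissue %in% sim$spec$tissues)
  sim$gene_info$gene_id[sim$gene_info$home_tissue == tissue]
}

#' Closed-form expected bias ratio under a simulation spec
#'
#' The analytic value of the pipeline's focus-codon tissue/genome ratio under
#' the generative model, in the infinite-data limit. The genome baseline is
#' the equal-weight mixture of the tissue preference vectors (gene shares and
#' length distributions are identical across home tissues); the tissue usage
#' is either the home tissue's own preference vector (`mode = "de_genes"`,
#' matching a pipeline run restricted to each tissue's DE list) or the
#' expression-weighted mixture with the home tissue up-weighted by `de_fold`
#' (`mode = "all_genes"`). Both vectors are max-normalized before the ratio,
#' exactly as in the pipeline.
#'
#' @param spec A `sim_spec`.
#' @param mode `"de_genes"` (default) or `"all_genes"`.
#' @return Matrix of expected ratios, rows = tissues, columns = focus codons.
#' @export
expected_bias <- function(spec, mode = c("de_genes", "all_genes")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "sim_spec"))
  pref <- tissue_preferences(spec)
  n_home <- table(factor(.home_tissues(spec), levels = spec$tissues))
  w_gene <- as.numeric(n_home) / spec$n_genes
  genome <- as.numeric(pref %*% w_gene)
  genome <- genome / max(genome)
  out <- matrix(NA_real_, nrow = length(spec$tissues),
                ncol = length(spec$focus_set),
                dimnames = list(spec$tissues, spec$focus_set))
  fi <- match(spec$focus_set, .CODONS)
  for (j in seq_along(spec$tissues)) {
    if (mode == "de_genes") {
      u <- pref[, j]
    } else {
      w <- w_gene * ifelse(seq_along(spec$tissues) == j, spec$de_fold, 1)
      u <- as.numeric(pref %*% (w / sum(w)))
    }
    u <- u / max(u)
    out[j, ] <- u[fi] / genome[fi]
  }
  out
}

# tissue x codon matrix -> nested named list (tissue -> codon -> value)
.bias_matrix_to_list <- function(m) {
  lapply(stats::setNames(rownames(m), rownames(m)),
         function(tt) as.list(m[tt, ]))
}

#' Write a synthetic dataset to disk
#'
#' Emits `cds.fa`, `counts.tsv`, one `de_<tissue>.txt` gene list per tissue,
#' and `truth.json` (spec parameters, home-tissue assignment, expected bias
#' ratios in both modes).
#'
#' @param spec A `sim_spec`.
#' @param dir Output directory (created if absent).
#' @return The `codon_sim`, invisibly; side effect: files under `dir`.
#' @export
simulate_dataset <- function(spec, dir) {
  sim <- generate_catalog(spec)
  counts <- generate_counts(sim)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cds_fasta(sim$catalog, file.path(dir, "cds.fa"))
  lines <- c(paste(c("gene_id", colnames(counts)), collapse = "\t"),
             paste(rownames(counts),
                   apply(counts, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, file.path(dir, "counts.tsv"))
  for (tt in spec$tissues) {
    writeLines(de_genes(sim, tt),
               file.path(dir, paste0("de_", tt, ".txt")))
  }
  jsonlite::write_json(list(
    spec = list(
      n_genes = spec$n_genes, length_range = spec$length_range,
      tissues = spec$tissues, enrichment = as.list(spec$enrichment),
      focus_set = spec$focus_set, depth = spec$depth,
      dispersion = spec$dispersion, de_fold = spec$de_fold,
      size_factors = if (is.null(spec$size_factors)) NULL else
        as.list(spec$size_factors),
      gc3_bias = spec$gc3_bias, seed = spec$seed
    ),
    home_tissue = as.list(stats::setNames(sim$gene_info$home_tissue,
                                          sim$gene_info$gene_id)),
    expected_bias_de_genes = .bias_matrix_to_list(
      expected_bias(spec, "de_genes")),
    expected_bias_all_genes = .bias_matrix_to_list(
      expected_bias(spec, "all_genes"))
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = 10,
  pretty = TRUE)
  invisible(sim)
}
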