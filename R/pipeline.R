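# End-to-end orchestration: read -> validate -> longest isoform -> genome
# usage -> size factors -> normalize -> weighted usage -> max-normalize ->
# tissue/genome ratio, with all intermediates written to disk.

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

# Fixed-format writers so reruns are byte-identical.
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

#' Write a 64-row codon profile or count vector as TSV
#'
#' @param x A `codon_profile` or `codon_counts`.
#' @param path Output path. Columns: codon, value.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path) {
  v <- unclass(x)
  val <- if (inherits(x, "codon_counts")) as.character(v) else .fmt_num(v)
  lines <- c("codon\tvalue", paste(.CODONS, val, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 64-row codon profile TSV
#'
#' @param path File written by [write_profile_tsv()].
#' @param kind Profile kind to stamp on the result.
#' @return A `codon_profile`.
#' @export
read_profile_tsv <- function(path, kind = "FREQUENCY") {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  codon_profile(stats::setNames(tab$value, tab$codon), kind = kind)
}

#' Run the full tissue codon usage bias pipeline
#'
#' Executes every stage of the analysis in order and writes all artifacts to
#' `out_dir`: `genome_usage.tsv` (max-normalized genome baseline),
#' `size_factors.tsv`, one `<tissue>_usage.tsv` per tissue (max-normalized),
#' `bias_report.tsv`, and `bias_report.json` (tissues, focus set, flags,
#' n_genes_used, size factors). Rerunning on identical inputs reproduces
#' byte-identical tables.
#'
#' @param config Named list, or path to a YAML file, with fields:
#'   \describe{
#'     \item{cds_fasta}{CDS FASTA path (required).}
#'     \item{counts}{expression TSV path (required).}
#'     \item{out_dir}{output directory (required; created if absent).}
#'     \item{tissues}{columns to analyse (default: all).}
#'     \item{gene_lists}{optional named list tissue -> gene-list file.}
#'     \item{pre_normalized}{counts already normalized (default FALSE).}
#'     \item{focus_set}{codon set of interest (default ACT, ACC).}
#'     \item{ratio_threshold}{focus flag threshold (default 1.1).}
#'     \item{mode}{"scaled" or "frequency" ratio mode (default "scaled").}
#'     \item{strict}{treat frameshifted/internal-stop CDS as errors
#'       (default TRUE; FALSE counts leniently).}
#'     \item{max_zero_rows}{size-factor pseudo-reference relaxation
#'       (default 0).}
#'   }
#' @return A `bias_report`, invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- .stage("config", yaml::read_yaml(config))
  }
  stopifnot(is.list(config))
  for (f in c("cds_fasta", "counts", "out_dir")) {
    if (is.null(config[[f]])) {
      stop(sprintf("[config] missing required field '%s'", f), call. = FALSE)
    }
  }
  focus_set <- config$focus_set %||% c("ACT", "ACC")
  threshold <- config$ratio_threshold %||% 1.1
  mode <- config$mode %||% "scaled"
  strict <- config$strict %||% TRUE
  lenient <- !strict

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  .log_stage("read", "reading CDS FASTA: ", config$cds_fasta)
  catalog <- .stage("read", read_cds_fasta(config$cds_fasta))
  .log_stage("read", nrow(catalog), " transcripts")

  .log_stage("validate", "validating CDS records")
  rep <- .stage("validate", validate_catalog(catalog))
  bad <- grepl("NOT_MULTIPLE_OF_3|INTERNAL_STOP", rep$flags)
  if (any(bad)) {
    if (strict) {
      stop("[validate] ", sum(bad), " CDS with frameshift/internal stop ",
           "(first: ", rep$transcript_id[which(bad)[1L]],
           "); set strict: false to count leniently", call. = FALSE)
    }
    .log_stage("validate", sum(bad), " CDS flagged; counting leniently")
  }

  .log_stage("isoforms", "selecting longest isoform per gene")
  catalog <- .stage("isoforms", select_longest_isoform(catalog))
  .log_stage("isoforms", nrow(catalog), " genes retained")

  .log_stage("genome", "aggregating genome codon usage")
  genome <- .stage("genome", aggregate_genome_usage(catalog, lenient = lenient))
  genome_scaled <- max_normalize_usage(genome$profile)
  write_profile_tsv(genome_scaled, file.path(config$out_dir,
                                             "genome_usage.tsv"))

  .log_stage("counts", "reading expression table: ", config$counts)
  m <- .stage("counts", read_expression_table(config$counts))
  tissues <- config$tissues %||% colnames(m)
  missing <- setdiff(tissues, colnames(m))
  if (length(missing)) {
    stop("[counts] tissue column(s) absent: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  if (isTRUE(config$pre_normalized)) {
    .log_stage("normalize", "counts declared pre-normalized; skipping")
    norm <- normalize_counts(m, pre_normalized = TRUE)
    sf <- stats::setNames(rep(1, ncol(m)), colnames(m))
  } else {
    .log_stage("normalize", "estimating median-of-ratios size factors")
    sf <- .stage("normalize", median_of_ratios_size_factors(
      m, max_zero_rows = config$max_zero_rows %||% 0L))
    norm <- normalize_counts(m, size_factors = sf)
  }
  writeLines(c("sample\tsize_factor",
               paste(names(sf), .fmt_num(sf), sep = "\t")),
             file.path(config$out_dir, "size_factors.tsv"))

  usages <- lapply(tissues, function(tt) {
    gl <- NULL
    if (!is.null(config$gene_lists) && !is.null(config$gene_lists[[tt]])) {
      gl <- .stage("gene_list", read_gene_list(config$gene_lists[[tt]]))
      .log_stage("usage", tt, ": restricting to ", length(gl),
                 " listed genes")
    }
    .log_stage("usage", "weighted codon usage for ", tt)
    u <- .stage("usage", weighted_codon_usage(catalog, norm, tt,
                                              gene_list = gl,
                                              lenient = lenient))
    u <- max_normalize_usage(u)
    write_profile_tsv(u$scaled_usage,
                      file.path(config$out_dir, paste0(tt, "_usage.tsv")))
    u
  })

  .log_stage("bias", "computing tissue/genome bias ratios")
  report <- .stage("bias", compare_tissues(
    usages, genome_scaled, focus_set = focus_set,
    ratio_threshold = threshold, mode = mode))

  tab <- as.data.frame(report)
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], .fmt_num)
  lines <- c(paste(colnames(tab), collapse = "\t"),
             do.call(paste, c(unname(tab), sep = "\t")))
  writeLines(lines, file.path(config$out_dir, "bias_report.tsv"))

  jsonlite::write_json(
    list(
      tissues = report$tissues,
      focus_set = report$focus_set,
      ratio_threshold = report$ratio_threshold,
      focus_flags = as.list(report$focus_flags),
      focus_ratios = lapply(stats::setNames(report$tissues, report$tissues),
                            function(tt) {
                              as.list(report$ratios[report$focus_set, tt])
                            }),
      n_genes_used = lapply(stats::setNames(usages, report$tissues),
                            function(u) u$n_genes_used),
      size_factors = as.list(sf)
    ),
    file.path(config$out_dir, "bias_report.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE
  )
  .log_stage("bias", "done; outputs in ", config$out_dir)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
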