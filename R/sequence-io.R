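# sequence_io: CDS FASTA and tabular input, isoform reduction, validation.

#' Construct a transcript catalog
#'
#' A transcript catalog is a data frame with one row per coding sequence and
#' columns `transcript_id`, `gene_id`, `seq` and `length_nt`. Row order is the
#' input order and is preserved by every operation in the package. Sequences
#' are upper-cased, `U` is mapped to `T`, and IUPAC ambiguity letters are
#' mapped to `N` on ingest, so `seq` is always over the alphabet {A,C,G,T,N}.
#'
#' @param transcript_id Character vector of unique transcript identifiers.
#' @param gene_id Character vector of gene identifiers (same length).
#' @param seq Character vector of CDS strings.
#' @return An object of class `transcript_catalog` (also a `data.frame`).
#' @export
transcript_catalog <- function(transcript_id, gene_id, seq) {
  transcript_id <- as.character(transcript_id)
  gene_id <- as.character(gene_id)
  seq <- .clean_seq(as.character(seq))
  if (length(transcript_id) != length(gene_id) ||
      length(transcript_id) != length(seq)) {
    stop("transcript_id, gene_id and seq must have equal length", call. = FALSE)
  }
  if (any(!nzchar(transcript_id))) {
    stop("empty transcript_id", call. = FALSE)
  }
  dup <- transcript_id[duplicated(transcript_id)]
  if (length(dup)) {
    stop("duplicate transcript_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(seq))) {
    stop("empty sequence for: ",
         paste(transcript_id[!nzchar(seq)], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    transcript_id = transcript_id,
    gene_id = gene_id,
    seq = seq,
    length_nt = nchar(seq),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("transcript_catalog", "data.frame")
  out
}

# Upper-case, RNA -> DNA, IUPAC ambiguity letters -> N; reject anything else.
.clean_seq <- function(seq) {
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  seq <- chartr("RYSWKMBDHV", "NNNNNNNNNN", seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("sequence contains characters outside the DNA alphabet (record ",
         which(bad)[1L], ")", call. = FALSE)
  }
  seq
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat(sprintf("<transcript_catalog> %d transcripts, %d genes\n",
              nrow(x), length(unique(x$gene_id))))
  if (nrow(x)) {
    show <- utils::head(x, 5L)
    show$seq <- ifelse(nchar(show$seq) > 24,
                       paste0(substr(show$seq, 1, 21), "..."), show$seq)
    print.data.frame(show)
    if (nrow(x) > 5L) cat("... and", nrow(x) - 5L, "more\n")
  }
  invisible(x)
}

#' Transcripts grouped by gene
#'
#' @param catalog A `transcript_catalog`.
#' @return Named list, gene_id -> character vector of transcript_ids, in the
#'   order genes first appear in the catalog.
#' @export
catalog_by_gene <- function(catalog) {
  split(catalog$transcript_id, factor(catalog$gene_id,
                                      levels = unique(catalog$gene_id)))
}

# Default FASTA header rule: first whitespace token is the transcript_id;
# gene_id from a "gene=..." key if present, otherwise the transcript_id with a
# trailing isoform suffix ("-RA" FlyBase style, or ".1") stripped.
.default_id_rule <- function(header) {
  tid <- sub("\\s.*$", "", header)
  m <- regmatches(header, regexpr("gene=[^\\s;]+", header, perl = TRUE))
  if (length(m) && nzchar(m)) {
    gid <- sub("^gene=", "", m)
  } else if (grepl("-R[A-Z]$", tid)) {
    gid <- sub("-R[A-Z]$", "", tid)
  } else if (grepl("\\.[0-9]+$", tid)) {
    gid <- sub("\\.[0-9]+$", "", tid)
  } else {
    gid <- tid
  }
  c(tid, gid)
}

#' Read a CDS FASTA file into a transcript catalog
#'
#' Accepts plain or gzip-compressed, wrapped or unwrapped multi-record FASTA.
#' Records keep their file order. Sequences are normalized as described in
#' [transcript_catalog()].
#'
#' @param path Path to the FASTA file.
#' @param id_rule Function mapping a FASTA header (without the leading `>`) to
#'   `c(transcript_id, gene_id)`. The default takes the first whitespace token
#'   as the transcript id and derives the gene id from a `gene=` key when
#'   present, else by stripping a trailing isoform suffix (`-RA`, `.1`).
#' @return A `transcript_catalog`.
#' @export
read_cds_fasta <- function(path, id_rule = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(id_rule)) id_rule <- .default_id_rule
  if (file.size(path) == 0L) {
    return(transcript_catalog(character(), character(), character()))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(transcript_catalog(character(), character(), character()))
  }
  ids <- vapply(names(set), id_rule, character(2L), USE.NAMES = FALSE)
  transcript_catalog(ids[1L, ], ids[2L, ], as.character(set))
}

#' Write a transcript catalog to FASTA
#'
#' Headers take the form `transcript_id gene=gene_id`, which round-trips
#' through [read_cds_fasta()] with the default header rule.
#'
#' @param catalog A `transcript_catalog`.
#' @param path Output path (plain text, unwrapped).
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(catalog, path) {
  set <- Biostrings::BStringSet(catalog$seq)
  names(set) <- paste0(catalog$transcript_id, " gene=", catalog$gene_id)
  Biostrings::writeXStringSet(set, path, width = 20000L)
  invisible(path)
}

#' Validate one coding sequence
#'
#' Advisory structural checks on a CDS: frame, start codon, internal stop,
#' terminal stop, ambiguous bases. Counting a frameshifted CDS is meaningless,
#' so pipelines running in strict mode treat `NOT_MULTIPLE_OF_3` and
#' `INTERNAL_STOP` as hard errors; here nothing is raised, only reported.
#'
#' @param seq A CDS string (or a single-row `transcript_catalog`).
#' @param require_start Flag `NO_START_ATG` when the CDS does not begin ATG.
#' @param require_stop Flag `NO_TERMINAL_STOP` when the final codon is not a
#'   stop triplet.
#' @return A list with `transcript_id` (NA for a bare string), `flags`
#'   (character subset of NOT_MULTIPLE_OF_3, NO_START_ATG, INTERNAL_STOP,
#'   NO_TERMINAL_STOP, AMBIGUOUS_BASES) and `n_ambiguous_codons` (in-frame
#'   codons containing a non-ACGT character).
#' @export
validate_cds <- function(seq, require_start = TRUE, require_stop = TRUE) {
  tid <- NA_character_
  if (inherits(seq, "transcript_catalog")) {
    stopifnot(nrow(seq) == 1L)
    tid <- seq$transcript_id
    seq <- seq$seq
  }
  seq <- .clean_seq(seq)
  n <- nchar(seq)
  flags <- character()
  if (n %% 3L != 0L) flags <- c(flags, "NOT_MULTIPLE_OF_3")
  if (require_start && substr(seq, 1L, 3L) != "ATG") {
    flags <- c(flags, "NO_START_ATG")
  }
  n3 <- n %/% 3L
  cods <- if (n3 > 0L) {
    starts <- 3L * seq_len(n3) - 2L
    substring(seq, starts, starts + 2L)
  } else character()
  n_amb <- sum(grepl("N", cods, fixed = TRUE))
  if (n_amb > 0L) flags <- c(flags, "AMBIGUOUS_BASES")
  if (n3 > 1L && any(cods[-n3] %in% .STOP_CODONS)) {
    flags <- c(flags, "INTERNAL_STOP")
  }
  if (require_stop && (n3 == 0L || !cods[n3] %in% .STOP_CODONS)) {
    flags <- c(flags, "NO_TERMINAL_STOP")
  }
  list(transcript_id = tid, flags = flags, n_ambiguous_codons = n_amb)
}

#' Validate every CDS in a catalog
#'
#' @param catalog A `transcript_catalog`.
#' @inheritParams validate_cds
#' @return Data frame with columns `transcript_id`, `flags` (comma-joined,
#'   empty string when clean) and `n_ambiguous_codons`.
#' @export
validate_catalog <- function(catalog, require_start = TRUE,
                             require_stop = TRUE) {
  reps <- lapply(catalog$seq, validate_cds,
                 require_start = require_start, require_stop = require_stop)
  data.frame(
    transcript_id = catalog$transcript_id,
    flags = vapply(reps, function(r) paste(r$flags, collapse = ","), ""),
    n_ambiguous_codons = vapply(reps, function(r) r$n_ambiguous_codons, 0L),
    stringsAsFactors = FALSE
  )
}

#' Reduce a catalog to one representative CDS per gene
#'
#' Keeps, for each gene, the transcript with the longest CDS; equal lengths
#' are resolved by the lexicographically smallest transcript_id so the result
#' is reproducible. Output order is the order in which genes first appear.
#'
#' @param catalog A non-empty `transcript_catalog`.
#' @return A `transcript_catalog` with exactly one row per gene. Idempotent.
#' @export
select_longest_isoform <- function(catalog) {
  if (nrow(catalog) == 0L) stop("empty catalog", call. = FALSE)
  genes <- unique(catalog$gene_id)
  pick <- vapply(genes, function(g) {
    i <- which(catalog$gene_id == g)
    i <- i[catalog$length_nt[i] == max(catalog$length_nt[i])]
    i[order(catalog$transcript_id[i])][1L]
  }, integer(1L))
  out <- catalog[pick, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transcript_catalog", "data.frame")
  out
}

# Open a possibly gzip-compressed text file for reading.
.open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read an expression count table
#'
#' Expects a TSV with a header row of sample/tissue names and transcript or
#' gene IDs in the first column. All values must be non-negative numbers and
#' row IDs unique.
#'
#' @param path Path to the TSV (plain or gzip).
#' @return Numeric matrix (rows = transcripts/genes, columns = samples) with
#'   a `size_factors` attribute left unset (`NULL`).
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- .open_text(path)
  on.exit(close(con))
  tab <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("expression table needs an ID column and at least ",
                           "one sample column", call. = FALSE)
  ids <- tab[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate row ID: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(tab[-1L], function(col) as.numeric(col), numeric(nrow(tab)))
  )
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(ids, colnames(tab)[-1L]))
  if (anyNA(vals)) stop("non-numeric cell in expression table", call. = FALSE)
  if (any(vals < 0)) stop("negative value in expression table", call. = FALSE)
  attr(vals, "size_factors") <- NULL
  vals
}

#' Read a plain-text gene list
#'
#' One ID per line; blank lines and lines starting with `#` are ignored;
#' duplicates are dropped.
#'
#' @param path Path to the list (plain or gzip).
#' @return Character vector of unique gene IDs.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- .open_text(path)
  on.exit(close(con))
  lines <- trimws(readLines(con, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}
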