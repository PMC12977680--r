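# Independent oracles and small fixture builders used across the suite.

ALL_CODONS <- codons()
SENSE <- codons(sense_only = TRUE)
STOPS <- c("TAA", "TAG", "TGA")

# Naive elongator-codon recount, written as a plain position-by-position loop
# (deliberately a different algorithm from the package's vectorized counter).
naive_elongator_count <- function(seq) {
  seq <- toupper(seq)
  out <- stats::setNames(integer(64L), ALL_CODONS)
  n <- nchar(seq) - nchar(seq) %% 3L
  ncod <- n %/% 3L
  if (ncod >= 2L) {
    for (i in 2:ncod) {
      cod <- substr(seq, 3L * i - 2L, 3L * i)
      if (i == ncod && cod %in% STOPS) next         # terminal stop
      if (grepl("[^ACGT]", cod)) next               # ambiguous codon
      out[cod] <- out[cod] + 1L
    }
  }
  list(counts = out, total = sum(out[SENSE]))
}

# Random in-frame CDS over ACGT with optional ambiguous bases; guaranteed to
# start ATG and end TAA so it is a structurally valid CDS unless n_rate > 0.
random_cds <- function(n_codons, n_rate = 0, internal_stops = FALSE) {
  pool <- if (internal_stops) ALL_CODONS else SENSE
  body <- sample(pool, n_codons, replace = TRUE)
  s <- paste0("ATG", paste(body, collapse = ""), "TAA")
  if (n_rate > 0) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < n_rate)
    hit <- hit[hit > 3]                             # keep the ATG intact
    ch[hit] <- "N"
    s <- paste(ch, collapse = "")
  }
  s
}

# Tiny catalog built directly from sequences.
make_catalog <- function(seqs, genes = NULL) {
  n <- length(seqs)
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(n))
  transcript_catalog(sprintf("%s.t1", genes), genes, seqs)
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

write_temp_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
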