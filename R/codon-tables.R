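# Fixed codon index shared by every 64-slot vector in the package.

.BASES <- c("A", "C", "G", "T")

# All 64 codons in lexicographic order AAA -> TTT. Every CodonCountVector and
# CodonUsageProfile is indexed in this order.
.CODONS <- sort(as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0)))

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.SENSE_CODONS <- setdiff(.CODONS, .STOP_CODONS)
.SENSE_IDX <- match(.SENSE_CODONS, .CODONS)

# One-letter amino acid per codon ("*" for stops), standard genetic code.
.codon_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[.CODONS])
}

#' The 64 codons in the package's fixed order
#'
#' All codon count vectors and usage profiles produced by this package are
#' indexed by this lexicographic order (AAA, AAC, ..., TTT).
#'
#' @param sense_only If `TRUE`, drop the three stop codons (TAA, TAG, TGA).
#' @return Character vector of codon strings.
#' @export
#' @examples
#' codons()[1:4]
#' length(codons(sense_only = TRUE))
codons <- function(sense_only = FALSE) {
  if (sense_only) .SENSE_CODONS else .CODONS
}

#' Amino acid translation for each of the 64 codons
#'
#' @return Named character vector (names = codons, values = one-letter amino
#'   acid codes, `"*"` for stop codons), in the package codon order.
#' @export
codon_amino_acids <- function() {
  stats::setNames(.codon_aa(), .CODONS)
}

# Validate a user-supplied codon set: length-3 strings over ACGT.
.check_codon_set <- function(codon_set) {
  codon_set <- toupper(as.character(codon_set))
  if (length(codon_set) == 0L) {
    stop("codon_set must contain at least one codon", call. = FALSE)
  }
  bad <- codon_set[!codon_set %in% .CODONS]
  if (length(bad)) {
    stop("invalid codon(s): ", paste(bad, collapse = ", "),
         " (expected length-3 strings over A/C/G/T)", call. = FALSE)
  }
  unique(codon_set)
}
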