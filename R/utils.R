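# Small shared helpers: base-level sequence ops on plain character vectors.
# Heavier sequence machinery (FASTA IO, whole-CDS translation) goes through
# Biostrings; these exist because per-base string surgery on a DNAString is
# slower and noisier than chartr/substr at this scale.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Complement of DNA bases
#'
#' @param x character vector of bases or base strings (A/C/G/T only).
#' @return complemented string(s), same orientation.
#' @keywords internal
comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Reverse complement of DNA strings
#' @param x character vector of DNA strings.
#' @return reverse-complemented string(s).
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a codon with the standard genetic code
#'
#' @param codon character vector of 3-mers over A/C/G/T.
#' @return one-letter amino acids, "*" for stop.
#' @keywords internal
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Extract bases from a locus sequence by genomic position
#'
#' @param sequence locus sequence (single string).
#' @param locus_offset genomic position of its first base.
#' @param gpos genomic positions (vector ok).
#' @param len number of bases per extraction (default 1).
#' @return character vector of substrings.
#' @keywords internal
seq_at <- function(sequence, locus_offset, gpos, len = 1L) {
  i <- gpos - locus_offset + 1L
  substring(sequence, i, i + len - 1L)
}

# stop() with a class so tests can assert on the failure category
fail <- function(msg, class) {
  stop(structure(
    class = c(class, "ttnsift_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
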