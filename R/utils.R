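# Small shared helpers. Sequences are handled internally as upper-case
# character strings; Biostrings is used at format boundaries.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity characters are complemented; gaps are preserved.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revComp <- function(x) {
  up <- toupper(x)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", up)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# split a nucleotide string into complete codons, dropping any trailing
# partial codon
splitCodons <- function(nt) {
  n <- nchar(nt)
  k <- n %/% 3L
  if (k == 0L) return(character(0))
  substring(nt, 3L * seq_len(k) - 2L, 3L * seq_len(k))
}

# TRUE where a character is an unambiguous base
isUnambiguousBase <- function(chars) chars %in% DNA_BASES

# character matrix (taxa x columns) from named sequences of equal length
seqsToMatrix <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

matrixToSeqs <- function(m) {
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

# deterministic sub-seed derivation, kept < 2^31 (double arithmetic to
# avoid integer overflow)
deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) + 100003 * as.numeric(i)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
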