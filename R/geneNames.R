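# Gene-name normalization. NCBI mitochondrial annotations are heterogeneous
# (COI vs COX1 vs "cytochrome c oxidase subunit I"); the synonym table
# shipped in extdata is a hand-curated reconciliation and can be extended by
# the user at call time.

.synonymEnv <- new.env(parent = emptyenv())

loadSynonymTable <- function() {
  if (!is.null(.synonymEnv$tab)) return(.synonymEnv$tab)
  path <- system.file("extdata", "gene_synonyms.tsv", package = "mitocompare")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .synonymEnv$tab <- stats::setNames(tab$norm_name, tab$synonym)
  .synonymEnv$tab
}

# uppercase and strip everything that is not A-Z or 0-9, so that
# "cox-1", "COX 1" and "CoxI" all collapse to one key
canonicalKey <- function(x) {
  gsub("[^A-Z0-9]", "", toupper(x))
}

#' Normalize a mitochondrial gene name
#'
#' Maps heterogeneous annotation labels (\code{COI}, \code{nd4l},
#' \code{"cytochrome c oxidase subunit I"}, ...) onto the canonical names of
#' the 12 shared protein-coding genes. The match is case-insensitive and
#' ignores punctuation and whitespace. Names with no match return
#' \code{"OTHER"}; the function is total and never errors.
#'
#' @param raw character vector of annotated names.
#' @param extra optional named character vector of additional synonyms
#'   (names = raw labels, values = normalized names) consulted before the
#'   shipped table.
#' @return character vector over \{COX1..ATP6, OTHER\}.
#' @examples
#' normalizeGeneName(c("ND4L", "cytb", "hypothetical protein"))
#' @export
normalizeGeneName <- function(raw, extra = NULL) {
  tab <- loadSynonymTable()
  if (!is.null(extra)) {
    ex <- stats::setNames(as.character(extra), canonicalKey(names(extra)))
    tab <- c(ex, tab)  # user entries take precedence
  }
  key <- canonicalKey(raw)
  out <- unname(tab[key])
  out[is.na(out)] <- "OTHER"
  out[is.na(raw) | raw == ""] <- "OTHER"
  out
}
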