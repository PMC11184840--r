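#' Annotated circular mitochondrial genome
#'
#' Central container for one mitogenome: the stored-strand nucleotide
#' sequence, its feature table (CDS/tRNA/rRNA with normalized gene names and
#' 0-based half-open coordinates), ordered taxonomy labels and life-trait
#' labels.
#'
#' Feature coordinates use 0-based half-open \code{[start, end)} intervals on
#' the stored strand; features spanning the origin of the circular molecule
#' carry \code{wraps_origin = TRUE} and have \code{end <= start}, meaning the
#' occupied interval is \code{[start, L) + [0, end)}.
#'
#' @slot id species/accession identifier.
#' @slot sequence upper-case nucleotide string (IUPAC alphabet).
#' @slot isCircular logical flag.
#' @slot features data.frame with columns \code{raw_name}, \code{norm_name},
#'   \code{type} (\code{CDS}/\code{tRNA}/\code{rRNA}), \code{start},
#'   \code{end}, \code{strand} (\code{"+"}/\code{"-"}), \code{frame_offset}
#'   (0/1/2, from GenBank \code{codon_start} - 1), \code{wraps_origin}.
#' @slot taxonomy named character vector ordered coarse to fine
#'   (class ... genus); may be empty.
#' @slot traits named character vector (feeding_habit, habitat,
#'   reproduction); \code{NA} marks missing.
#' @export
setClass("Mitogenome",
  representation(
    id = "character",
    sequence = "character",
    isCircular = "logical",
    features = "data.frame",
    taxonomy = "character",
    traits = "character"
  )
)

PCG_NAMES <- c("COX1", "COX2", "COX3", "CYTB", "NAD1", "NAD2", "NAD3",
               "NAD4", "NAD4L", "NAD5", "NAD6", "ATP6")

setValidity("Mitogenome", function(object) {
  msg <- character()
  L <- nchar(object@sequence)
  if (length(object@sequence) != 1L || L == 0L)
    msg <- c(msg, "sequence must be a single non-empty string")
  f <- object@features
  need <- c("raw_name", "norm_name", "type", "start", "end", "strand",
            "frame_offset", "wraps_origin")
  if (!all(need %in% names(f))) {
    msg <- c(msg, paste("features must have columns:",
                        paste(need, collapse = ", ")))
  } else if (nrow(f)) {
    bad <- !f$wraps_origin & !(f$start >= 0 & f$start < f$end & f$end <= L)
    if (any(bad))
      msg <- c(msg, "non-wrapping features need 0 <= start < end <= length")
    if (any(f$frame_offset < 0 | f$frame_offset > 2))
      msg <- c(msg, "frame_offset must be in 0..2")
    pcg <- f$norm_name[f$type == "CDS" & f$norm_name %in% PCG_NAMES]
    if (anyDuplicated(pcg))
      msg <- c(msg, paste("duplicated PCG annotation:",
                          paste(unique(pcg[duplicated(pcg)]), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' In-frame coding sequence for one protein-coding gene
#'
#' The nucleotide string is on the coding strand, frame-trimmed so that the
#' first base of the first codon is position 1, and truncated to complete
#' codons (incomplete terminal stop codons are truncated, never padded).
#'
#' @slot speciesId source genome identifier.
#' @slot gene normalized PCG name (COX1 ... ATP6).
#' @slot nt coding-strand nucleotide string, length = 3 * nCodons.
#' @slot nCodons number of complete codons.
#' @slot hasInternalStop TRUE if a TAA/TAG stop occurs before the final codon
#'   under the invertebrate mitochondrial code.
#' @slot sourceStrand strand of the gene on the stored genome strand.
#' @export
setClass("CodingSequence",
  representation(
    speciesId = "character",
    gene = "character",
    nt = "character",
    nCodons = "integer",
    hasInternalStop = "logical",
    sourceStrand = "character"
  )
)

setValidity("CodingSequence", function(object) {
  msg <- character()
  if (nchar(object@nt) != 3L * object@nCodons)
    msg <- c(msg, "nt length must equal 3 * nCodons")
  if (!object@sourceStrand %in% c("+", "-"))
    msg <- c(msg, "sourceStrand must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

#' Codon-aware alignment block
#'
#' One gene alignment (or the concatenated PCG-genome) as equal-length rows
#' over \code{A,C,G,T}, IUPAC ambiguity codes and \code{-}, with per-column
#' codon-position (1/2/3) and gene-of-column annotations.
#'
#' @slot gene gene name, or \code{"PCG-genome"} for a concatenation.
#' @slot seqs named character vector of aligned rows (equal lengths).
#' @slot codonPositionOfColumn integer vector over \{1,2,3\}, cycling within
#'   each gene segment.
#' @slot geneOfColumn character vector naming the gene each column belongs to.
#' @slot allGap named logical: taxa whose rows are entirely gaps for some
#'   gene segment (filled in by \code{concatenateBlocks}).
#' @export
setClass("AlignmentBlock",
  representation(
    gene = "character",
    seqs = "character",
    codonPositionOfColumn = "integer",
    geneOfColumn = "character",
    allGap = "logical"
  )
)

setValidity("AlignmentBlock", function(object) {
  msg <- character()
  w <- unique(nchar(object@seqs))
  if (length(w) > 1L)
    msg <- c(msg, "aligned rows must have equal length")
  if (length(w) == 1L && w != length(object@codonPositionOfColumn))
    msg <- c(msg, "codonPositionOfColumn must match alignment width")
  if (length(object@geneOfColumn) != length(object@codonPositionOfColumn))
    msg <- c(msg, "geneOfColumn must match alignment width")
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    msg <- c(msg, "rows must carry unique taxon names")
  if (length(msg)) msg else TRUE
})

## ---- accessors ------------------------------------------------------------

#' @rdname Mitogenome-class
#' @param object,x a \code{Mitogenome}.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname Mitogenome-class
#' @export
setMethod("genomeId", "Mitogenome", function(x) x@id)

#' @rdname Mitogenome-class
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname Mitogenome-class
#' @export
setMethod("genomeSequence", "Mitogenome", function(x) x@sequence)

#' @rdname Mitogenome-class
#' @export
setGeneric("genomeFeatures", function(x) standardGeneric("genomeFeatures"))
#' @rdname Mitogenome-class
#' @export
setMethod("genomeFeatures", "Mitogenome", function(x) x@features)

#' @rdname CodingSequence-class
#' @param x a \code{CodingSequence}.
#' @export
setGeneric("codingNt", function(x) standardGeneric("codingNt"))
#' @rdname CodingSequence-class
#' @export
setMethod("codingNt", "CodingSequence", function(x) x@nt)

#' @rdname AlignmentBlock-class
#' @param x an \code{AlignmentBlock}.
#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))
#' @rdname AlignmentBlock-class
#' @export
setMethod("alignedSeqs", "AlignmentBlock", function(x) x@seqs)

#' @rdname AlignmentBlock-class
#' @export
setGeneric("codonPositions", function(x) standardGeneric("codonPositions"))
#' @rdname AlignmentBlock-class
#' @export
setMethod("codonPositions", "AlignmentBlock",
          function(x) x@codonPositionOfColumn)

setMethod("show", "Mitogenome", function(object) {
  f <- object@features
  cat("Mitogenome '", object@id, "': ", nchar(object@sequence), " bp, ",
      if (object@isCircular) "circular" else "linear", "\n", sep = "")
  cat("  features: ", sum(f$type == "CDS"), " CDS, ",
      sum(f$type == "tRNA"), " tRNA, ", sum(f$type == "rRNA"), " rRNA\n",
      sep = "")
})

setMethod("show", "CodingSequence", function(object) {
  cat("CodingSequence ", object@speciesId, "/", object@gene, ": ",
      object@nCodons, " codons, strand ", object@sourceStrand,
      if (object@hasInternalStop) ", internal stop(s)" else "", "\n", sep = "")
})

setMethod("show", "AlignmentBlock", function(object) {
  cat("AlignmentBlock '", object@gene, "': ", length(object@seqs),
      " taxa x ", nchar(object@seqs[1]), " columns\n", sep = "")
})
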