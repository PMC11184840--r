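# Codon-aware alignment ingestion, concatenation and resolved-site masks.
#
# Alignments are consumed, never produced: the reading frame is trusted from
# the input (plus an optional leading offset), and no realignment is
# attempted. Within any taxon, a codon containing a gap or ambiguity is
# treated as unresolved as a whole codon.

CANONICAL_GENE_ORDER <- c("COX1", "COX2", "COX3", "CYTB", "NAD1", "NAD2",
                          "NAD3", "NAD4", "NAD4L", "NAD5", "NAD6", "ATP6")

#' Read a per-gene codon alignment from aligned FASTA
#'
#' @param path aligned FASTA file; all rows equal length.
#' @param gene gene name recorded on the block (default: file name stem).
#' @param offset number of leading columns to drop before assigning codon
#'   positions (for alignments that do not start in frame).
#' @return an \code{\linkS4class{AlignmentBlock}} with codon positions
#'   cycling 1,2,3.
#' @export
readAlignment <- function(path, gene = NULL,
                          offset = 0L) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- stats::setNames(toupper(as.character(set)), names(set))
  # FASTA headers may carry descriptions; keep the first token as the taxon
  names(seqs) <- sub("[[:space:]].*$", "", names(seqs))
  widths <- unique(nchar(seqs))
  if (length(widths) != 1L)
    stop("ragged alignment in ", path, ": row lengths ",
         paste(sort(widths), collapse = ", "))
  if (offset > 0L) seqs <- substr(seqs, offset + 1L, widths)
  w <- unique(nchar(seqs))
  if (w %% 3L != 0L)
    stop("alignment width ", w, " in ", path, " is not a multiple of 3; ",
         "supply 'offset' to trim leading out-of-frame columns")
  if (is.null(gene))
    gene <- toupper(sub("\\.[^.]*$", "", basename(path)))
  new("AlignmentBlock", gene = gene, seqs = seqs,
      codonPositionOfColumn = rep(1:3, length.out = w),
      geneOfColumn = rep(gene, w),
      allGap = stats::setNames(logical(length(seqs)), names(seqs)))
}

#' Per-taxon reading-frame report
#'
#' Counts internal stop codons (TAA/TAG under the invertebrate mitochondrial
#' code) among each taxon's gap-free codons. The final codon of a row is not
#' counted as internal.
#'
#' @param block an \code{\linkS4class{AlignmentBlock}}.
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @return data.frame: taxon, n_codons_checked, n_internal_stops, and a
#'   comma-separated list of stop codon indices (1-based codon numbers).
#' @export
checkReadingFrame <- function(block, code = geneticCode()) {
  out <- lapply(names(block@seqs), function(tx) {
    codons <- splitCodons(block@seqs[[tx]])
    clean <- vapply(codons, function(cd)
      all(isUnambiguousBase(strsplit(cd, "")[[1]])), logical(1))
    stops <- which(clean & isStopCodon(codons, code))
    stops <- stops[stops < length(codons)]  # terminal stop is legitimate
    data.frame(taxon = tx, n_codons_checked = sum(clean),
               n_internal_stops = length(stops),
               stop_codon_indices = paste(stops, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Concatenate per-gene alignments into a PCG-genome block
#'
#' Blocks are arranged in the canonical mitochondrial gene order
#' (COX1, COX2, COX3, CYTB, NAD1..NAD6, ATP6 by default). Taxa missing from
#' a gene receive an all-gap segment there and are flagged; a taxon present
#' in no block is an error.
#'
#' @param blocks list of \code{\linkS4class{AlignmentBlock}} objects.
#' @param taxaOrder optional character vector fixing row order.
#' @param geneOrder character vector overriding the canonical order.
#' @return an \code{\linkS4class{AlignmentBlock}} named
#'   \code{"PCG-genome"}; slot \code{allGap} flags taxa that received at
#'   least one all-gap segment.
#' @export
concatenateBlocks <- function(blocks, taxaOrder = NULL,
                              geneOrder = CANONICAL_GENE_ORDER) {
  names(blocks) <- vapply(blocks, function(b) b@gene, character(1))
  known <- intersect(geneOrder, names(blocks))
  extra <- setdiff(names(blocks), geneOrder)
  blocks <- blocks[c(known, extra)]
  allTaxa <- unique(unlist(lapply(blocks, function(b) names(b@seqs))))
  if (is.null(taxaOrder)) taxaOrder <- allTaxa
  orphan <- setdiff(taxaOrder, allTaxa)
  if (length(orphan))
    stop("taxa present in no alignment block: ",
         paste(orphan, collapse = ", "))
  segs <- lapply(blocks, function(b) {
    w <- nchar(b@seqs[[1]])
    s <- stats::setNames(rep(strrep("-", w), length(taxaOrder)), taxaOrder)
    present <- intersect(taxaOrder, names(b@seqs))
    s[present] <- b@seqs[present]
    s
  })
  seqs <- stats::setNames(
    vapply(taxaOrder,
           function(tx) paste(vapply(segs, `[[`, character(1), tx),
                              collapse = ""),
           character(1)),
    taxaOrder)
  flag <- vapply(taxaOrder, function(tx)
    any(vapply(blocks, function(b) !tx %in% names(b@seqs), logical(1))),
    logical(1))
  new("AlignmentBlock", gene = "PCG-genome", seqs = seqs,
      codonPositionOfColumn = unlist(lapply(blocks, function(b)
        b@codonPositionOfColumn), use.names = FALSE),
      geneOfColumn = unlist(lapply(blocks, function(b) b@geneOfColumn),
                            use.names = FALSE),
      allGap = flag)
}

#' Slice a gene segment back out of a concatenated block
#'
#' @param block a concatenated \code{\linkS4class{AlignmentBlock}}.
#' @param gene gene name to extract.
#' @return the per-gene \code{AlignmentBlock}.
#' @export
sliceGene <- function(block, gene) {
  idx <- which(block@geneOfColumn == gene)
  if (!length(idx)) stop("gene ", gene, " not present in block")
  seqs <- vapply(block@seqs, function(s)
    paste(substring(s, idx, idx), collapse = ""), character(1))
  new("AlignmentBlock", gene = gene, seqs = seqs,
      codonPositionOfColumn = block@codonPositionOfColumn[idx],
      geneOfColumn = block@geneOfColumn[idx],
      allGap = stats::setNames(logical(length(seqs)), names(seqs)))
}

#' Resolved-site masks for an alignment
#'
#' A column is resolved when every taxon in the subset carries an
#' unambiguous A/C/G/T there; the pairwise mask marks, per taxon pair, the
#' columns where both members are unambiguous. Resolved implies
#' pairwise-resolved for every pair.
#'
#' @param block an \code{\linkS4class{AlignmentBlock}}.
#' @param taxaSubset taxa to consider (default: all).
#' @return list with \code{resolved} (logical vector over columns) and
#'   \code{pairwise} (logical matrix, one row per unordered pair named
#'   \code{"a|b"}).
#' @export
buildSiteMask <- function(block, taxaSubset = names(block@seqs)) {
  if (!length(taxaSubset)) stop("empty taxa subset")
  if (!all(taxaSubset %in% names(block@seqs)))
    stop("taxa not in block: ",
         paste(setdiff(taxaSubset, names(block@seqs)), collapse = ", "))
  m <- seqsToMatrix(block@seqs[taxaSubset])
  ok <- matrix(m %in% DNA_BASES, nrow = nrow(m))
  resolved <- colSums(ok) == nrow(ok)
  pairs <- utils::combn(taxaSubset, 2L)
  pw <- matrix(FALSE, ncol(pairs), ncol(m),
               dimnames = list(paste(pairs[1, ], pairs[2, ], sep = "|"),
                               NULL))
  for (j in seq_len(ncol(pairs))) {
    pw[j, ] <- ok[match(pairs[1, j], taxaSubset), ] &
      ok[match(pairs[2, j], taxaSubset), ]
  }
  list(resolved = resolved, pairwise = pw)
}

#' Write a concatenated alignment and its partition table
#'
#' The partition table lists 1-based inclusive column ranges per gene in
#' RAxML-style \code{DNA, GENE = start-end} lines alongside a TSV.
#'
#' @param block concatenated \code{\linkS4class{AlignmentBlock}}.
#' @param dir output directory.
#' @return invisible character vector of written paths.
#' @export
writeConcatenated <- function(block, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "pcg_genome.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(block@seqs), fa,
                              width = 70L)
  genes <- rle(block@geneOfColumn)
  ends <- cumsum(genes$lengths)
  starts <- ends - genes$lengths + 1L
  tab <- data.frame(gene = genes$values, start = starts, end = ends)
  tsv <- file.path(dir, "partitions.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rax <- file.path(dir, "partitions.txt")
  writeLines(sprintf("DNA, %s = %d-%d", tab$gene, tab$start, tab$end), rax)
  invisible(c(fa, tsv, rax))
}
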