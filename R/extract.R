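# PCG extraction, COX1 orientation and completeness checks.

# genomic slice for one feature row, concatenating across the origin for
# wrapping features; returns the stored-strand sequence
featureSlice <- function(sequence, start, end, wraps) {
  L <- nchar(sequence)
  if (wraps) {
    paste0(substr(sequence, start + 1L, L), substr(sequence, 1L, end))
  } else {
    substr(sequence, start + 1L, end)
  }
}

#' Extract in-frame coding sequences for the 12 mitochondrial PCGs
#'
#' For each annotated protein-coding gene the genomic slice is taken
#' (concatenated across the origin for wrapping features),
#' reverse-complemented for minus-strand genes, trimmed of
#' \code{frame_offset} leading nucleotides, and truncated to complete
#' codons. Incomplete terminal stop codons (completed by polyadenylation in
#' vivo) are truncated, never padded. Internal stops are detected under the
#' invertebrate mitochondrial code (stops TAA/TAG; a stop at any codon
#' before the final one counts as internal).
#'
#' @param genome a \code{\linkS4class{Mitogenome}}.
#' @param code a \code{\linkS4class{GeneticCode}} (default table 5).
#' @return named list of \code{\linkS4class{CodingSequence}} objects, one
#'   per PCG present, in canonical gene order.
#' @export
extractPcgs <- function(genome, code = geneticCode()) {
  f <- genome@features
  pcgRows <- which(f$type == "CDS" & f$norm_name %in% PCG_NAMES)
  dup <- f$norm_name[pcgRows][duplicated(f$norm_name[pcgRows])]
  if (length(dup)) {
    stop("duplicate PCG annotation in ", genome@id, ": ",
         paste(unique(dup), collapse = ", "), " (features ",
         paste(pcgRows, collapse = ", "), ")")
  }
  out <- list()
  for (i in pcgRows) {
    nt <- featureSlice(genome@sequence, f$start[i], f$end[i],
                       f$wraps_origin[i])
    if (f$strand[i] == "-") nt <- revComp(nt)
    off <- f$frame_offset[i]
    if (off > 0L) nt <- substr(nt, off + 1L, nchar(nt))
    codons <- splitCodons(nt)
    if (length(codons) < 2L)
      stop("CDS ", f$norm_name[i], " in ", genome@id,
           " shorter than 2 codons after frame trimming")
    nt <- paste(codons, collapse = "")
    stops <- isStopCodon(codons, code)
    internal <- any(stops[-length(stops)])
    out[[f$norm_name[i]]] <- new("CodingSequence",
      speciesId = genome@id, gene = f$norm_name[i], nt = nt,
      nCodons = length(codons), hasInternalStop = internal,
      sourceStrand = f$strand[i])
  }
  out[order(match(names(out), PCG_NAMES))]
}

# remap one feature interval under rotation by r on a circle of length L
rotateInterval <- function(start, end, wraps, r, L) {
  s <- (start - r) %% L
  e <- (end - r) %% L
  if (e == 0L) e <- L
  list(start = s, end = e, wraps = s >= e)
}

#' Orient a circular genome to start at COX1
#'
#' Rotates the sequence so the COX1 start is index 0 on the plus strand,
#' reverse-complementing the whole genome first if COX1 is annotated on the
#' minus strand, and remaps every feature coordinate. A pure rotation leaves
#' every composition metric unchanged; the reverse-complement step flips the
#' sign of strand skews (and is recorded in the paper trail by the feature
#' strands themselves).
#'
#' @param genome a circular \code{\linkS4class{Mitogenome}} containing COX1.
#' @return the re-oriented \code{Mitogenome}.
#' @export
orientToCox1 <- function(genome) {
  if (!genome@isCircular)
    stop("genome ", genome@id,
         " is not circular; orientation is defined only for circular ",
         "molecules (rotation would drop origin-spanning context)")
  f <- genome@features
  ci <- which(f$type == "CDS" & f$norm_name == "COX1")
  if (!length(ci)) stop("COX1 absent from ", genome@id)
  ci <- ci[1]
  L <- nchar(genome@sequence)

  if (f$strand[ci] == "-") {
    # flip the whole molecule; [s, e) on one strand maps to [L-e, L-s)
    genome@sequence <- revComp(genome@sequence)
    for (i in seq_len(nrow(f))) {
      if (f$wraps_origin[i]) {
        s <- (L - f$end[i]) %% L
        e <- (2L * L - f$start[i]) %% L
        if (e == 0L) e <- L
        f$start[i] <- s; f$end[i] <- e
        f$wraps_origin[i] <- s >= e
      } else {
        ns <- L - f$end[i]; ne <- L - f$start[i]
        f$start[i] <- ns; f$end[i] <- ne
      }
      f$strand[i] <- if (f$strand[i] == "+") "-" else "+"
    }
  }

  r <- f$start[ci]
  if (r != 0L) {
    genome@sequence <- paste0(substr(genome@sequence, r + 1L, L),
                              substr(genome@sequence, 1L, r))
    for (i in seq_len(nrow(f))) {
      ri <- rotateInterval(f$start[i], f$end[i], f$wraps_origin[i], r, L)
      f$start[i] <- ri$start; f$end[i] <- ri$end
      f$wraps_origin[i] <- ri$wraps
    }
  }
  genome@features <- f
  methods::validObject(genome)
  genome
}

#' Genome completeness report
#'
#' A genome is complete when it has all 12 PCGs, 22 tRNAs, 2 rRNAs and is
#' circularized.
#'
#' @param genome a \code{\linkS4class{Mitogenome}}.
#' @return data.frame row with \code{n_pcgs}, \code{n_trnas}, \code{n_rrnas},
#'   \code{circularized}, \code{is_complete}.
#' @export
completenessReport <- function(genome) {
  f <- genome@features
  nP <- length(unique(f$norm_name[f$type == "CDS" &
                                  f$norm_name %in% PCG_NAMES]))
  nT <- sum(f$type == "tRNA")
  nR <- sum(f$type == "rRNA")
  data.frame(species_id = genome@id, n_pcgs = nP, n_trnas = nT,
             n_rrnas = nR, circularized = genome@isCircular,
             is_complete = nP == 12L && nT == 22L && nR == 2L &&
               genome@isCircular,
             stringsAsFactors = FALSE)
}

#' Write coding sequences to per-gene multi-species FASTA files
#'
#' @param cdsList list of \code{\linkS4class{CodingSequence}} objects
#'   (possibly across species).
#' @param dir output directory; one \code{GENE.fasta} per gene.
#' @return invisible character vector of written paths.
#' @export
writeCodingFasta <- function(cdsList, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genes <- unique(vapply(cdsList, function(x) x@gene, character(1)))
  paths <- character(0)
  for (g in genes) {
    sel <- Filter(function(x) x@gene == g, cdsList)
    seqs <- Biostrings::DNAStringSet(
      stats::setNames(vapply(sel, function(x) x@nt, character(1)),
                      vapply(sel, function(x) x@speciesId, character(1))))
    p <- file.path(dir, paste0(g, ".fasta"))
    Biostrings::writeXStringSet(seqs, p, width = 70L)
    paths <- c(paths, p)
  }
  invisible(paths)
}
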