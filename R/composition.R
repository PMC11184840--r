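# Composition statistics: lengths, %GC, GC/AT skews at genome, PCG-set,
# gene and codon-position resolution.
#
# Only unambiguous A/C/G/T are counted; IUPAC ambiguity characters and gaps
# are excluded from numerators and denominators alike, so an N-run cannot
# bias a skew. A zero denominator yields NA_real_, the package-wide
# "undefined" sentinel, which group summaries exclude (with a count).

baseCounts <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  c(A = sum(ch == "A"), C = sum(ch == "C"),
    G = sum(ch == "G"), T = sum(ch == "T"))
}

#' GC skew of a nucleotide sequence
#'
#' \code{(G - C) / (G + C)} counting only unambiguous G and C on the given
#' strand. Returns \code{NA} when the sequence contains no G or C.
#'
#' @param seq nucleotide string.
#' @return skew in \code{[-1, 1]}, or \code{NA} if undefined.
#' @examples
#' gcSkew("GGGC")  # 0.5
#' @export
gcSkew <- function(seq) {
  n <- baseCounts(seq)
  d <- n[["G"]] + n[["C"]]
  if (d == 0) NA_real_ else (n[["G"]] - n[["C"]]) / d
}

#' AT skew of a nucleotide sequence
#'
#' \code{(A - T) / (A + T)}, the analogue of \code{\link{gcSkew}} for the
#' A/T pair.
#'
#' @inheritParams gcSkew
#' @return skew in \code{[-1, 1]}, or \code{NA} if undefined.
#' @export
atSkew <- function(seq) {
  n <- baseCounts(seq)
  d <- n[["A"]] + n[["T"]]
  if (d == 0) NA_real_ else (n[["A"]] - n[["T"]]) / d
}

#' Percent G+C content
#'
#' \code{100 (G + C) / (A + C + G + T)}; ambiguity characters are excluded
#' from both numerator and denominator.
#'
#' @inheritParams gcSkew
#' @return percent in \code{[0, 100]}, or \code{NA} on an empty count.
#' @export
pctGc <- function(seq) {
  n <- baseCounts(seq)
  d <- sum(n)
  if (d == 0) NA_real_ else 100 * (n[["G"]] + n[["C"]]) / d
}

#' GC skew at one codon position of a coding sequence
#'
#' Takes every third nucleotide starting at the requested position of a
#' frame-trimmed coding sequence and returns its \code{\link{gcSkew}}.
#'
#' @param cds a \code{\linkS4class{CodingSequence}} or a frame-trimmed
#'   nucleotide string whose length is a multiple of 3.
#' @param position codon position, 1, 2 or 3.
#' @return skew or \code{NA}.
#' @export
codonPositionSkew <- function(cds, position) {
  if (!position %in% 1:3) stop("codon position must be 1, 2 or 3")
  nt <- if (methods::is(cds, "CodingSequence")) cds@nt else cds
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length is not a multiple of 3")
  idx <- seq.int(position, n, by = 3L)
  sub <- paste(substring(nt, idx, idx), collapse = "")
  gcSkew(sub)
}

#' Full composition record for one genome
#'
#' Genome-level metrics are computed on the full stored strand (including
#' rRNA, tRNA and noncoding regions); per-gene and codon-position metrics on
#' the coding strand of each extracted PCG.
#'
#' @param genome a \code{\linkS4class{Mitogenome}}.
#' @param cdss list of \code{\linkS4class{CodingSequence}} objects extracted
#'   from \code{genome} (default: extracted here).
#' @return list with components \code{summary} (one-row data.frame:
#'   species_id, genome_length, pcg_total_length, pcg_proportion,
#'   genome_pct_gc, pcg_pct_gc, genome/pcg GC and AT skews), \code{perGene}
#'   (gene, length, pct_gc, gc_skew, at_skew) and \code{perCodonPosition}
#'   (gene, position, gc_skew).
#' @export
genomeSummary <- function(genome, cdss = extractPcgs(genome)) {
  if (!length(cdss)) stop("genome ", genome@id, " has zero extracted PCGs")
  pcgConcat <- paste(vapply(cdss, function(x) x@nt, character(1)),
                     collapse = "")
  perGene <- do.call(rbind, lapply(cdss, function(x) data.frame(
    species_id = genome@id, gene = x@gene, length = nchar(x@nt),
    pct_gc = pctGc(x@nt), gc_skew = gcSkew(x@nt), at_skew = atSkew(x@nt),
    stringsAsFactors = FALSE)))
  rownames(perGene) <- NULL
  perPos <- do.call(rbind, lapply(cdss, function(x) data.frame(
    species_id = genome@id, gene = x@gene, position = 1:3,
    gc_skew = vapply(1:3, function(p) codonPositionSkew(x, p), numeric(1)),
    stringsAsFactors = FALSE)))
  rownames(perPos) <- NULL
  L <- nchar(genome@sequence)
  pcgLen <- sum(perGene$length)
  summary <- data.frame(
    species_id = genome@id,
    genome_length = L,
    pcg_total_length = pcgLen,
    pcg_proportion = pcgLen / L,
    genome_pct_gc = pctGc(genome@sequence),
    pcg_pct_gc = pctGc(pcgConcat),
    genome_gc_skew = gcSkew(genome@sequence),
    genome_at_skew = atSkew(genome@sequence),
    pcg_gc_skew = gcSkew(pcgConcat),
    pcg_at_skew = atSkew(pcgConcat),
    stringsAsFactors = FALSE)
  list(summary = summary, perGene = perGene, perCodonPosition = perPos)
}

#' Bind composition records across genomes
#'
#' @param records list of results from \code{\link{genomeSummary}}.
#' @return list of three data.frames (\code{summary}, \code{perGene},
#'   \code{perCodonPosition}) stacked across species.
#' @export
compositionTable <- function(records) {
  list(summary = do.call(rbind, lapply(records, `[[`, "summary")),
       perGene = do.call(rbind, lapply(records, `[[`, "perGene")),
       perCodonPosition = do.call(rbind,
                                  lapply(records, `[[`, "perCodonPosition")))
}

#' Per-group summary statistics of composition metrics
#'
#' Groups species by a clade, taxonomic-rank or trait label and reports per
#' group and metric: n, mean, sample standard deviation, min, max, and the
#' number of undefined (NA) values excluded. Species with a missing group
#' label are excluded and counted; groups left empty are omitted with a
#' warning.
#'
#' @param summaryTable the \code{summary} data.frame from
#'   \code{\link{compositionTable}} (or any species-by-metric data.frame
#'   with a \code{species_id} column and numeric metric columns).
#' @param grouping named character vector mapping species_id to group label
#'   (NA = missing).
#' @return long-format data.frame: group, metric, n, mean, sd, min, max,
#'   n_excluded. Single-member groups report \code{sd = NA}.
#' @export
cladeSummary <- function(summaryTable, grouping) {
  lab <- grouping[summaryTable$species_id]
  keep <- !is.na(lab)
  if (!all(keep))
    message(sum(!keep), " species without a group label excluded")
  tab <- summaryTable[keep, , drop = FALSE]
  lab <- lab[keep]
  metrics <- names(tab)[vapply(tab, is.numeric, logical(1))]
  out <- list()
  for (g in unique(lab)) {
    sub <- tab[lab == g, , drop = FALSE]
    if (!nrow(sub)) { warning("group ", g, " empty after exclusions"); next }
    for (m in metrics) {
      v <- sub[[m]]
      ok <- !is.na(v)
      out[[length(out) + 1L]] <- data.frame(
        group = g, metric = m, n = sum(ok),
        mean = if (any(ok)) mean(v[ok]) else NA_real_,
        sd = if (sum(ok) > 1L) stats::sd(v[ok]) else NA_real_,
        min = if (any(ok)) min(v[ok]) else NA_real_,
        max = if (any(ok)) max(v[ok]) else NA_real_,
        n_excluded = sum(!ok), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write composition tables as TSV files
#'
#' Emits one wide species-by-metric table, a long per-gene table, and the
#' heatmap-ready species-by-(gene, codon position) GC-skew matrix. An
#' optional Newick tree fixes the species (row) order to the tree's tip
#' order.
#'
#' @param tables result of \code{\link{compositionTable}}.
#' @param dir output directory.
#' @param treePath optional Newick file whose tip order determines row order.
#' @return invisible character vector of written paths.
#' @export
writeCompositionTables <- function(tables, dir, treePath = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ord <- tables$summary$species_id
  if (!is.null(treePath)) {
    tips <- ape::read.tree(treePath)$tip.label
    ord <- c(intersect(tips, ord), setdiff(ord, tips))
  }
  s <- tables$summary[match(ord, tables$summary$species_id), , drop = FALSE]
  p1 <- file.path(dir, "composition_summary.tsv")
  utils::write.table(s, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "composition_per_gene.tsv")
  utils::write.table(tables$perGene, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # wide heatmap matrix: rows = species, columns = gene.pos
  pp <- tables$perCodonPosition
  pp$key <- paste0(pp$gene, ".pos", pp$position)
  wide <- stats::reshape(pp[, c("species_id", "key", "gc_skew")],
                         idvar = "species_id", timevar = "key",
                         direction = "wide")
  names(wide) <- sub("^gc_skew\\.", "", names(wide))
  wide <- wide[match(ord, wide$species_id), , drop = FALSE]
  p3 <- file.path(dir, "codon_position_gc_skew.tsv")
  utils::write.table(wide, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
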