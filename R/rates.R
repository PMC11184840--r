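# Pairwise synonymous / non-synonymous substitution rates by a
# Nei-Gojobori-type counting estimator under the invertebrate mitochondrial
# genetic code, averaged per ingroup sequence over a reference outgroup
# panel.
#
# Sites: each codon position contributes the fraction of its single-
# nucleotide changes that are synonymous, with changes creating stop codons
# excluded from that position's denominator; n = 3 - s, so site counts are
# conserved exactly (S + N = 3 x codons). Differences between codons are
# classified along all minimal single-step paths that avoid stop codons,
# with equal path weights. Proportions are corrected with the Jukes-Cantor
# form d = -(3/4) ln(1 - (4/3) p), which saturates at p >= 3/4.

.ratesEnv <- new.env(parent = emptyenv())

PERMS <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

#' Synonymous and non-synonymous site counts of a codon
#'
#' @param codon a sense codon (no ambiguity, not a stop).
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @return named numeric \code{c(s = , n = )} with \code{s + n = 3}.
#' @examples
#' countSites("TTT")  # s = 1/3 under table 5
#' @export
countSites <- function(codon, code = geneticCode()) {
  codon <- toupper(codon)
  ch <- strsplit(codon, "", fixed = TRUE)[[1]]
  if (length(ch) != 3L || !all(ch %in% DNA_BASES))
    stop("ambiguous or malformed codon: ", codon)
  if (isStopCodon(codon, code)) stop("stop codon has no site counts: ", codon)
  aa <- code@codonMap[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; denom <- 0L
    for (b in setdiff(DNA_BASES, ch[pos])) {
      nb <- ch; nb[pos] <- b
      ncod <- paste(nb, collapse = "")
      if (isStopCodon(ncod, code)) next
      denom <- denom + 1L
      if (code@codonMap[[ncod]] == aa) syn <- syn + 1L
    }
    if (denom > 0L) s <- s + syn / denom
  }
  c(s = s, n = 3 - s)
}

# memoized site table over all sense codons
siteCountTable <- function(code = geneticCode()) {
  key <- paste0("sites_", code@id)
  if (!is.null(.ratesEnv[[key]])) return(.ratesEnv[[key]])
  tab <- t(vapply(code@senseCodons, countSites, numeric(2), code = code))
  .ratesEnv[[key]] <- tab
  tab
}

#' Classify the differences between two codons
#'
#' All minimal single-step mutational paths between the codons are
#' enumerated; paths passing through a stop codon are discarded and the
#' synonymous/non-synonymous step counts are averaged with equal weights
#' over the remaining paths. If every path passes through a stop the
#' classification falls back to all paths (stop "amino acid" treated as
#' non-matching) and is flagged.
#'
#' @param codonA,codonB sense codons without ambiguity.
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @return named numeric \code{c(sd = , nd = )}; \code{sd + nd} equals the
#'   Hamming distance of the pair. Attribute \code{stop_path} is TRUE when
#'   the stop-free constraint had to be dropped.
#' @export
countDifferences <- function(codonA, codonB, code = geneticCode()) {
  codonA <- toupper(codonA); codonB <- toupper(codonB)
  key <- paste0("diff_", code@id)
  if (is.null(.ratesEnv[[key]]))
    .ratesEnv[[key]] <- new.env(parent = emptyenv())
  cache <- .ratesEnv[[key]]
  ck <- if (codonA <= codonB) paste0(codonA, codonB) else
    paste0(codonB, codonA)
  hit <- cache[[ck]]
  if (!is.null(hit)) return(hit)

  chA <- strsplit(codonA, "", fixed = TRUE)[[1]]
  chB <- strsplit(codonB, "", fixed = TRUE)[[1]]
  if (!all(c(chA, chB) %in% DNA_BASES))
    stop("ambiguous codon in pair: ", codonA, "/", codonB)
  if (isStopCodon(codonA, code) || isStopCodon(codonB, code))
    stop("stop codon in pair: ", codonA, "/", codonB)
  diffPos <- which(chA != chB)
  k <- length(diffPos)
  if (k == 0L) {
    res <- c(sd = 0, nd = 0); attr(res, "stop_path") <- FALSE
    cache[[ck]] <- res
    return(res)
  }

  walkPath <- function(order, allowStops) {
    cur <- chA; s <- 0L; n <- 0L
    for (pos in order) {
      nxt <- cur; nxt[pos] <- chB[pos]
      ncod <- paste(nxt, collapse = "")
      if (!allowStops && isStopCodon(ncod, code)) return(NULL)
      aaCur <- code@codonMap[[paste(cur, collapse = "")]]
      aaNxt <- code@codonMap[[ncod]]
      if (aaCur == aaNxt && aaCur != "*") s <- s + 1L else n <- n + 1L
      cur <- nxt
    }
    c(s, n)
  }

  orders <- lapply(PERMS[[as.character(k)]], function(p) diffPos[p])
  legal <- Filter(Negate(is.null), lapply(orders, walkPath,
                                          allowStops = FALSE))
  stopPath <- FALSE
  if (!length(legal)) {
    legal <- lapply(orders, walkPath, allowStops = TRUE)
    stopPath <- TRUE
  }
  acc <- Reduce(`+`, legal) / length(legal)
  res <- c(sd = acc[1], nd = acc[2])
  attr(res, "stop_path") <- stopPath
  cache[[ck]] <- res
  res
}

# split two aligned rows into comparable codons: both fully unambiguous
# A/C/G/T and neither a stop (internal stops are masked per pair, not
# dropped with the whole sequence)
comparableCodons <- function(seqA, seqB, code) {
  ca <- splitCodons(seqA); cb <- splitCodons(seqB)
  k <- min(length(ca), length(cb))
  ca <- ca[seq_len(k)]; cb <- cb[seq_len(k)]
  cleanA <- !grepl("[^ACGT]", ca); cleanB <- !grepl("[^ACGT]", cb)
  keep <- cleanA & cleanB
  keep[keep] <- !(isStopCodon(ca[keep], code) | isStopCodon(cb[keep], code))
  list(a = ca[keep], b = cb[keep])
}

#' Pairwise dN/dS estimate for two aligned coding rows
#'
#' Codons carrying a gap, ambiguity character or stop codon in either taxon
#' are masked pairwise. Expected site counts are averaged over the two
#' sequences; proportions of differences are corrected with the
#' Jukes-Cantor form. Status becomes \code{saturated_dS} /
#' \code{saturated_dN} when the respective proportion reaches the
#' correction's domain boundary (3/4), and \code{insufficient_sites} when
#' fewer than \code{minCodons} codons remain comparable.
#'
#' @param seqA,seqB aligned, frame-consistent nucleotide rows (equal
#'   length, multiple of 3).
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @param minCodons minimum comparable codons for an estimate (default 30).
#' @param taxonA,taxonB labels recorded in the result.
#' @param gene gene label recorded in the result.
#' @return one-row data.frame: taxon_a, taxon_b, gene, n_codons_compared,
#'   S_sites, N_sites, Sd, Nd, pS, pN, dS, dN, omega, status.
#' @export
ng86Pairwise <- function(seqA, seqB, code = geneticCode(), minCodons = 30L,
                         taxonA = "a", taxonB = "b", gene = NA_character_) {
  if (nchar(seqA) != nchar(seqB))
    stop("aligned rows differ in length (", nchar(seqA), " vs ",
         nchar(seqB), ")")
  cc <- comparableCodons(toupper(seqA), toupper(seqB), code)
  nC <- length(cc$a)
  base <- data.frame(taxon_a = taxonA, taxon_b = taxonB, gene = gene,
                     n_codons_compared = nC, S_sites = NA_real_,
                     N_sites = NA_real_, Sd = NA_real_, Nd = NA_real_,
                     pS = NA_real_, pN = NA_real_, dS = NA_real_,
                     dN = NA_real_, omega = NA_real_, status = "ok",
                     stringsAsFactors = FALSE)
  if (nC < minCodons) {
    base$status <- "insufficient_sites"
    return(base)
  }
  st <- siteCountTable(code)
  sA <- sum(st[cc$a, "s"]); sB <- sum(st[cc$b, "s"])
  S <- (sA + sB) / 2
  N <- 3 * nC - S
  diffIdx <- which(cc$a != cc$b)
  Sd <- 0; Nd <- 0
  for (i in diffIdx) {
    d <- countDifferences(cc$a[i], cc$b[i], code)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  base$S_sites <- S; base$N_sites <- N; base$Sd <- Sd; base$Nd <- Nd
  base$pS <- pS; base$pN <- pN
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  if (pS >= 0.75) {
    base$status <- "saturated_dS"
  } else if (pN >= 0.75) {
    base$status <- "saturated_dN"
  } else {
    base$dS <- jc(pS); base$dN <- jc(pN)
    base$omega <- if (base$dS > 0) base$dN / base$dS else NA_real_
  }
  base
}

#' Outgroup-averaged substitution rates for one ingroup sequence
#'
#' Runs \code{\link{ng86Pairwise}} of the ingroup row against each outgroup
#' row and averages dN and dS over the status-ok pairs, mirroring the
#' five-outgroup standardization design. The ratio is computed from the
#' averaged rates (ratio of means, not mean of ratios), which is robust to
#' near-zero dS in single pairs. Saturated or insufficient pairs are
#' skipped and the number of contributing outgroups recorded; an entry with
#' none is flagged missing.
#'
#' @param ingroupSeq aligned row for the ingroup species.
#' @param outgroupSeqs named character vector of aligned outgroup rows.
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @param minCodons passed to \code{\link{ng86Pairwise}}.
#' @param speciesId,gene labels for the result row.
#' @return one-row data.frame: species_id, gene, dN_mean, dS_mean, omega,
#'   n_outgroups_used, missing, status (semicolon-joined pair statuses).
#' @export
averageOverOutgroups <- function(ingroupSeq, outgroupSeqs,
                                 code = geneticCode(), minCodons = 30L,
                                 speciesId = "ingroup",
                                 gene = NA_character_) {
  est <- lapply(names(outgroupSeqs), function(og)
    ng86Pairwise(ingroupSeq, outgroupSeqs[[og]], code, minCodons,
                 taxonA = speciesId, taxonB = og, gene = gene))
  est <- do.call(rbind, est)
  ok <- est$status == "ok"
  nUsed <- sum(ok)
  dN <- if (nUsed) mean(est$dN[ok]) else NA_real_
  dS <- if (nUsed) mean(est$dS[ok]) else NA_real_
  data.frame(species_id = speciesId, gene = gene,
             dN_mean = dN, dS_mean = dS,
             omega = if (nUsed && !is.na(dS) && dS > 0) dN / dS else NA_real_,
             n_outgroups_used = nUsed, missing = nUsed == 0L,
             status = paste(est$status, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Per-species, per-gene substitution-rate table
#'
#' For every gene alignment block, every non-outgroup taxon is compared to
#' the outgroup panel and the averaged rates collected into a long-format
#' table (12 genes x species when all genes are present).
#'
#' @param geneBlocks list of per-gene \code{\linkS4class{AlignmentBlock}}
#'   objects containing both ingroup and outgroup rows.
#' @param outgroupIds character vector of outgroup taxon ids.
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @param minCodons passed down.
#' @return data.frame with one row per species x gene.
#' @export
ratesTable <- function(geneBlocks, outgroupIds, code = geneticCode(),
                       minCodons = 30L) {
  out <- list()
  for (b in geneBlocks) {
    present <- intersect(outgroupIds, names(b@seqs))
    if (!length(present))
      warning("no outgroups present in block ", b@gene)
    ingroup <- setdiff(names(b@seqs), outgroupIds)
    ogs <- b@seqs[present]
    for (tx in ingroup) {
      out[[length(out) + 1L]] <- averageOverOutgroups(
        b@seqs[[tx]], ogs, code, minCodons, speciesId = tx, gene = b@gene)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write the rates table as TSV
#'
#' @param rates result of \code{\link{ratesTable}}.
#' @param path output file.
#' @return invisible \code{path}.
#' @export
writeRatesTable <- function(rates, path) {
  utils::write.table(rates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
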