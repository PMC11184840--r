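# Entropy-based mutational-saturation index with a Monte-Carlo
# full-saturation null.
#
# The observed index is the mean per-column Shannon entropy over resolved
# sites, normalized by the entropy of the pooled base frequencies of the
# taxa subset -- the expectation for a fully saturated alignment whose
# columns are iid draws from the pooled composition. Normalizing by pooled
# frequencies rather than log2(4) respects the extreme AT richness of
# mitochondrial data. The null distribution is simulated by drawing
# same-shaped alignments column-iid from the pooled frequencies; a z-score
# against that null drives the verdict bands.

#' Shannon entropy of one alignment column
#'
#' @param column character vector of resolved bases (A/C/G/T), length >= 2.
#' @return entropy in bits.
#' @examples
#' siteEntropy(c("A", "A", "C", "C"))  # 1 bit
#' @export
siteEntropy <- function(column) {
  if (!length(column)) stop("empty column")
  p <- tabulate(match(column, DNA_BASES), nbins = 4L)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# column entropies of a base-index matrix (rows = taxa), vectorized
columnEntropies <- function(idx) {
  nt <- nrow(idx)
  H <- numeric(ncol(idx))
  for (b in 1:4) {
    p <- colSums(idx == b) / nt
    nz <- p > 0
    H[nz] <- H[nz] - p[nz] * log2(p[nz])
  }
  H
}

# resolved-site base-index matrix and pooled frequencies for a taxa subset
resolvedIndexMatrix <- function(block, taxaSubset, codonPosition = NULL) {
  m <- seqsToMatrix(block@seqs[taxaSubset])
  cols <- seq_len(ncol(m))
  if (!is.null(codonPosition) && !identical(codonPosition, "all")) {
    cols <- cols[block@codonPositionOfColumn[cols] == as.integer(codonPosition)]
  }
  m <- m[, cols, drop = FALSE]
  idx <- matrix(match(m, DNA_BASES), nrow = nrow(m))
  resolved <- colSums(is.na(idx)) == 0L
  idx[, resolved, drop = FALSE]
}

#' Entropy-based saturation index of an alignment subset
#'
#' @param block an \code{\linkS4class{AlignmentBlock}}.
#' @param taxaSubset taxa to include (>= 4 required).
#' @param codonPosition 1, 2, 3 or \code{"all"}.
#' @param minSites minimum resolved sites (default 20).
#' @return list: \code{iss_obs}, \code{n_taxa}, \code{n_resolved_sites},
#'   \code{pooled_freqs}, \code{h_max}.
#' @export
iss <- function(block, taxaSubset = names(block@seqs),
                codonPosition = "all", minSites = 20L) {
  if (length(taxaSubset) < 4L)
    stop("need >= 4 taxa for the saturation index, got ",
         length(taxaSubset))
  idx <- resolvedIndexMatrix(block, taxaSubset, codonPosition)
  if (ncol(idx) < minSites)
    stop("need >= ", minSites, " resolved sites, got ", ncol(idx))
  f <- tabulate(idx, nbins = 4L)
  f <- f / sum(f)
  hMax <- -sum(f[f > 0] * log2(f[f > 0]))
  # a single-base subset has no diversity at all: index 0 by definition
  obs <- if (hMax == 0) 0 else mean(columnEntropies(idx)) / hMax
  list(iss_obs = obs, n_taxa = length(taxaSubset),
       n_resolved_sites = ncol(idx), pooled_freqs = f, h_max = hMax)
}

#' Monte-Carlo saturation test against a full-saturation null
#'
#' Simulates \code{nReps} alignments of the observed shape with every
#' column drawn iid multinomial from the pooled base frequencies (the
#' full-saturation expectation), computes the index for each, and reports a
#' z-score and one-sided p for the observed index lying below the null.
#' Verdict bands (configurable): \code{not_saturated} for z <= -6,
#' \code{saturated} for z >= -2, \code{substantial} in between.
#'
#' @param block an \code{\linkS4class{AlignmentBlock}}.
#' @param codonPosition 1, 2, 3 or \code{"all"}.
#' @param taxaSubset taxa to include.
#' @param nReps number of null replicates (>= 200).
#' @param seed mandatory integer seed.
#' @param cladeLabel label recorded on the result.
#' @param verdictBands numeric c(lower, upper) z thresholds.
#' @param minSites minimum resolved sites.
#' @return one-row data.frame: gene, codon_position, clade, n_taxa,
#'   n_resolved_sites, iss_obs, null_mean, null_sd, z, p_one_sided,
#'   verdict, n_reps, seed.
#' @export
saturationTest <- function(block, codonPosition = "all",
                           taxaSubset = names(block@seqs),
                           nReps = 500L, seed,
                           cladeLabel = "all",
                           verdictBands = c(-6, -2),
                           minSites = 20L) {
  if (missing(seed)) stop("a seed is mandatory for the saturation test")
  if (nReps < 200L) stop("nReps must be >= 200")
  obs <- iss(block, taxaSubset, codonPosition, minSites)
  nt <- obs$n_taxa; ns <- obs$n_resolved_sites
  f <- obs$pooled_freqs
  hMax <- obs$h_max
  nullIss <- numeric(nReps)
  set.seed(as.integer(seed))
  for (r in seq_len(nReps)) {
    idx <- matrix(sample.int(4L, nt * ns, replace = TRUE, prob = f),
                  nrow = nt)
    nullIss[r] <- mean(columnEntropies(idx)) / hMax
  }
  nullMean <- mean(nullIss); nullSd <- stats::sd(nullIss)
  z <- (obs$iss_obs - nullMean) / nullSd
  p <- (1 + sum(nullIss <= obs$iss_obs)) / (nReps + 1)
  verdict <- if (z <= verdictBands[1]) "not_saturated"
             else if (z >= verdictBands[2]) "saturated"
             else "substantial"
  data.frame(gene = block@gene,
             codon_position = as.character(codonPosition),
             clade = cladeLabel, n_taxa = nt, n_resolved_sites = ns,
             iss_obs = obs$iss_obs, null_mean = nullMean, null_sd = nullSd,
             z = z, p_one_sided = p, verdict = verdict,
             n_reps = nReps, seed = as.integer(seed),
             stringsAsFactors = FALSE)
}
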