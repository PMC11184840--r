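# Seeded synthetic mitogenome generator with full ground truth.
#
# Everything the pipeline consumes can be generated here: circular annotated
# genomes with prescribed %GC and codon-position GC skews, per-gene codon
# alignments diverged from a shared root at prescribed omega, a synthetic
# five-taxon outgroup panel (standing in for the tardigrade + arthropod
# reference panel), trait tables with planted effects, and a Newick guide
# tree. All randomness flows from a single mandatory seed.

DEFAULT_GENE_CODONS <- c(COX1 = 520L, COX2 = 230L, COX3 = 255L,
                         CYTB = 370L, NAD1 = 290L, NAD2 = 280L,
                         NAD3 = 115L, NAD4 = 410L, NAD4L = 80L,
                         NAD5 = 520L, NAD6 = 140L, ATP6 = 195L)

DEFAULT_CLADES <- c("Enoplea", "Tylenchina", "Rhabditina", "Spirurina")

DEFAULT_OUTGROUPS <- c("OUT_tardigrade_1", "OUT_tardigrade_2",
                       "OUT_arthropod_1", "OUT_arthropod_2",
                       "OUT_arthropod_3")

DEFAULT_FEEDING <- c("bacterivore", "fungivore", "plant_parasite",
                     "animal_parasite", "omnivore", "predator")
DEFAULT_HABITAT <- c("terrestrial", "freshwater", "marine",
                     "animal_associated", "insect_associated")
DEFAULT_REPRODUCTION <- c("amphimictic", "parthenogenetic",
                          "hermaphroditic")

#' Configuration for the synthetic mitogenome generator
#'
#' Defaults emulate the shape of a nematode mitogenome study panel: 12 PCGs
#' with realistic codon lengths (~10.2 kb coding), AT-rich composition
#' (25\% GC), the strongest G skew at the 3rd codon position, genomes of
#' ~14.5 kb, four clades, and purifying selection strongest in parasitic
#' feeding habits.
#'
#' @param nSpecies number of ingroup species.
#' @param seed mandatory integer seed.
#' @param geneCodons named integer vector of codon counts per gene
#'   (excluding the terminal stop codon appended to each gene).
#' @param targetGc target G+C fraction (0..1) of coding sequence.
#' @param posSkews length-3 numeric: target GC skew at codon positions
#'   1, 2, 3.
#' @param tIngroup,tOutgroup divergence from the shared root, in expected
#'   mutation proposals per nucleotide site.
#' @param kappa transition/transversion proposal weight (1 = unbiased,
#'   matched to the equal-weight site counting of the rate estimator).
#' @param omegaByFeeding named numeric: dN/dS acceptance ratio per feeding
#'   habit (parasites lowest, i.e. strongest purifying selection).
#' @param omegaOutgroup omega used on the outgroup branches.
#' @param skewSdUnit between-species standard deviation of the 3rd-position
#'   skew, the "sd unit" in which trait effects are expressed.
#' @param traitSkewShift named numeric: planted shift (in sd units) of the
#'   3rd-position GC skew per feeding-habit level.
#' @param minusStrandGenes genes annotated on the minus strand of the
#'   emitted genomes.
#' @param wrapOrigin if TRUE, rotate each genome so COX1 spans the origin
#'   (exercises origin-wrapping extraction).
#' @param clades clade labels cycled over species.
#' @param outgroupIds ids of the 5 synthetic outgroup taxa.
#' @return a list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(nSpecies = 20L, seed,
                            geneCodons = DEFAULT_GENE_CODONS,
                            targetGc = 0.25,
                            posSkews = c(0.2, -0.1, 0.45),
                            tIngroup = 0.15, tOutgroup = 0.5,
                            kappa = 1,
                            omegaByFeeding = c(bacterivore = 0.20,
                                               fungivore = 0.20,
                                               plant_parasite = 0.10,
                                               animal_parasite = 0.05,
                                               omnivore = 0.25,
                                               predator = 0.15),
                            omegaOutgroup = 0.10,
                            skewSdUnit = 0.05,
                            traitSkewShift = c(animal_parasite = -2,
                                               plant_parasite = 1),
                            minusStrandGenes = c("NAD2", "NAD5", "ATP6"),
                            wrapOrigin = FALSE,
                            clades = DEFAULT_CLADES,
                            outgroupIds = DEFAULT_OUTGROUPS) {
  if (missing(seed)) stop("a seed is mandatory in SyntheticConfig")
  stopifnot(all(geneCodons >= 2L), targetGc > 0, targetGc < 1,
            length(posSkews) == 3L, all(abs(posSkews) <= 1),
            tIngroup >= 0, tOutgroup >= 0, kappa > 0)
  structure(list(nSpecies = as.integer(nSpecies), seed = as.integer(seed),
                 geneCodons = geneCodons, targetGc = targetGc,
                 posSkews = posSkews, tIngroup = tIngroup,
                 tOutgroup = tOutgroup, kappa = kappa,
                 omegaByFeeding = omegaByFeeding,
                 omegaOutgroup = omegaOutgroup,
                 skewSdUnit = skewSdUnit,
                 traitSkewShift = traitSkewShift,
                 minusStrandGenes = minusStrandGenes,
                 wrapOrigin = wrapOrigin, clades = clades,
                 outgroupIds = outgroupIds),
            class = "SyntheticConfig")
}

#' Solve stop-free codon frequencies matching composition targets
#'
#' Iterative proportional fitting over the sense-codon simplex: position
#' marginals are matched to the targets implied by the requested GC
#' fraction and per-position GC skews (AT skew 0), with stop codons carrying
#' zero mass. Errors if the targets cannot be met, reporting the nearest
#' feasible point reached.
#'
#' @param targetGc G+C fraction in (0, 1), applied per position.
#' @param posSkews length-3 GC skews per codon position.
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @param tol maximum absolute marginal deviation accepted.
#' @return named numeric vector of frequencies over the sense codons.
#' @export
solveCodonFrequencies <- function(targetGc, posSkews,
                                  code = geneticCode(), tol = 1e-4) {
  target <- vapply(1:3, function(p) {
    g <- targetGc * (1 + posSkews[p]) / 2
    cc <- targetGc * (1 - posSkews[p]) / 2
    at <- (1 - targetGc) / 2
    c(A = at, C = cc, G = g, T = at)
  }, numeric(4))
  codons <- code@senseCodons
  baseAt <- lapply(1:3, function(p) substr(codons, p, p))
  w <- lapply(1:3, function(p) stats::setNames(rep(1, 4), DNA_BASES))
  q <- rep(1 / length(codons), length(codons))
  for (iter in 1:500) {
    q <- w[[1]][baseAt[[1]]] * w[[2]][baseAt[[2]]] * w[[3]][baseAt[[3]]]
    q <- q / sum(q)
    maxDev <- 0
    for (p in 1:3) {
      realized <- vapply(DNA_BASES, function(b)
        sum(q[baseAt[[p]] == b]), numeric(1))
      dev <- target[, p] - realized
      maxDev <- max(maxDev, abs(dev))
      adj <- ifelse(realized > 0, target[, p] / realized, 1)
      w[[p]] <- w[[p]] * adj
    }
    if (maxDev < tol / 4) break
  }
  q <- w[[1]][baseAt[[1]]] * w[[2]][baseAt[[2]]] * w[[3]][baseAt[[3]]]
  q <- stats::setNames(q / sum(q), codons)
  realized <- vapply(1:3, function(p) {
    r <- vapply(DNA_BASES, function(b) sum(q[baseAt[[p]] == b]), numeric(1))
    (r[["G"]] - r[["C"]]) / (r[["G"]] + r[["C"]])
  }, numeric(1))
  if (max(abs(realized - posSkews)) > 10 * tol)
    stop("composition targets infeasible for the stop-free codon alphabet; ",
         "nearest feasible per-position skews: ",
         paste(round(realized, 4), collapse = ", "))
  q
}

#' Sample a stop-free codon sequence with target composition
#'
#' @param nCodons number of codons (>= 2).
#' @param targetGc,posSkews composition targets, as in
#'   \code{\link{solveCodonFrequencies}}.
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @param seed integer seed.
#' @return nucleotide string of length 3 * nCodons with no stop codons;
#'   realized skews converge to the targets as nCodons grows.
#' @export
sampleCodonSequence <- function(nCodons, targetGc = 0.25,
                                posSkews = c(0.2, -0.1, 0.45),
                                code = geneticCode(), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (nCodons < 2L) stop("nCodons must be >= 2")
  q <- solveCodonFrequencies(targetGc, posSkews, code)
  set.seed(as.integer(seed))
  paste(sample(names(q), nCodons, replace = TRUE, prob = q), collapse = "")
}

# per-site accepted-substitution rate of the proposal process on a given
# ancestor, used to translate a target fraction of differing sites into a
# divergence time
acceptanceRate <- function(ancestorNt, omega, kappa, code) {
  codons <- splitCodons(ancestorNt)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  tot <- 0
  for (cd in unique(codons)) {
    cnt <- sum(codons == cd)
    ch <- strsplit(cd, "", fixed = TRUE)[[1]]
    aa <- code@codonMap[[cd]]
    for (pos in 1:3) {
      alts <- setdiff(DNA_BASES, ch[pos])
      wts <- ifelse(alts == transitions[[ch[pos]]], kappa, 1)
      wts <- wts / sum(wts)
      for (j in seq_along(alts)) {
        nb <- ch; nb[pos] <- alts[j]
        ncod <- paste(nb, collapse = "")
        acc <- if (isStopCodon(ncod, code)) 0
               else if (code@codonMap[[ncod]] == aa) 1 else omega
        tot <- tot + cnt * wts[j] * acc
      }
    }
  }
  tot / (3 * length(codons))  # accepted substitutions per site per unit t
}

#' Divergence time for a target fraction of differing sites
#'
#' @param ancestorNt ancestor coding sequence (no stops).
#' @param pDiff target fraction of nucleotide sites differing.
#' @param omega,kappa simulation parameters.
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @return proposal time t (per-site) giving approximately \code{pDiff}
#'   differing sites.
#' @export
divergenceTime <- function(ancestorNt, pDiff, omega, kappa = 1,
                           code = geneticCode()) {
  a <- acceptanceRate(ancestorNt, omega, kappa, code)
  -log(1 - pDiff) / a
}

#' Evolve a codon sequence for time t under selection strength omega
#'
#' Per-codon Gillespie simulation: every nucleotide site proposes single-
#' base changes at unit rate (targets weighted \code{kappa}:1 for
#' transitions), proposals creating stop codons are rejected, synonymous
#' proposals are accepted, and non-synonymous proposals are accepted with
#' probability \code{omega}. Every accepted event is logged as synonymous
#' or non-synonymous.
#'
#' @param ancestorNt coding-strand nucleotide string without stop codons,
#'   length a multiple of 3.
#' @param t divergence in expected proposals per site (>= 0).
#' @param omega non-synonymous acceptance probability (>= 0).
#' @param kappa transition proposal weight.
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @param seed integer seed.
#' @return list: \code{nt} (descendant), \code{sd_true}, \code{nd_true}
#'   (accepted synonymous / non-synonymous event counts),
#'   \code{n_proposals}.
#' @export
evolvePair <- function(ancestorNt, t, omega, kappa = 1,
                       code = geneticCode(), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (t < 0) stop("t must be >= 0")
  codons <- splitCodons(ancestorNt)
  if (any(isStopCodon(codons, code)))
    stop("ancestor contains stop codons; evolve only sense portions")
  set.seed(as.integer(seed))
  sdTrue <- 0L; ndTrue <- 0L; nProp <- 0L
  if (t > 0) {
    transitions <- c(A = "G", G = "A", C = "T", T = "C")
    nEvents <- stats::rpois(length(codons), 3 * t)
    for (i in which(nEvents > 0L)) {
      ch <- strsplit(codons[i], "", fixed = TRUE)[[1]]
      for (e in seq_len(nEvents[i])) {
        nProp <- nProp + 1L
        pos <- sample.int(3L, 1L)
        alts <- setdiff(DNA_BASES, ch[pos])
        wts <- ifelse(alts == transitions[[ch[pos]]], kappa, 1)
        b <- sample(alts, 1L, prob = wts)
        nb <- ch; nb[pos] <- b
        ncod <- paste(nb, collapse = "")
        if (isStopCodon(ncod, code)) next
        same <- code@codonMap[[ncod]] == code@codonMap[[paste(ch, collapse = "")]]
        if (same) {
          ch <- nb; sdTrue <- sdTrue + 1L
        } else if (stats::runif(1) < omega) {
          ch <- nb; ndTrue <- ndTrue + 1L
        }
      }
      codons[i] <- paste(ch, collapse = "")
    }
  }
  list(nt = paste(codons, collapse = ""), sd_true = sdTrue,
       nd_true = ndTrue, n_proposals = nProp)
}

# fourfold-degenerate codons of a code: all three 3rd-position changes are
# synonymous and stop-free
fourfoldCodons <- function(code) {
  st <- siteCountTable(code)
  prefixSyn <- vapply(code@senseCodons, function(cd) {
    ch <- strsplit(cd, "", fixed = TRUE)[[1]]
    fam <- paste0(ch[1], ch[2], DNA_BASES)
    all(fam %in% code@senseCodons) &&
      length(unique(code@codonMap[fam])) == 1L
  }, logical(1))
  code@senseCodons[prefixSyn]
}

# shift realized 3rd-position GC skew of a coding sequence by delta using
# synonymous C<->G swaps at fourfold-degenerate sites; returns the new
# sequence and the number of swaps (each a true synonymous substitution)
injectSkew <- function(nt, delta, code, ff = fourfoldCodons(code)) {
  if (delta == 0) return(list(nt = nt, n_swaps = 0L))
  codons <- splitCodons(nt)
  p3 <- substr(codons, 3L, 3L)
  g3 <- sum(p3 == "G"); c3 <- sum(p3 == "C")
  if (g3 + c3 == 0L) return(list(nt = nt, n_swaps = 0L))
  isFF <- codons %in% ff
  nTargetSwaps <- abs(delta) * (g3 + c3) / 2
  if (delta > 0) {           # G-ward: flip fourfold C -> G
    eligible <- which(isFF & p3 == "C")
  } else {                   # C-ward: flip fourfold G -> C
    eligible <- which(isFF & p3 == "G")
  }
  if (!length(eligible)) return(list(nt = nt, n_swaps = 0L))
  pFlip <- min(1, nTargetSwaps / length(eligible))
  flip <- eligible[stats::runif(length(eligible)) < pFlip]
  newBase <- if (delta > 0) "G" else "C"
  for (i in flip) substr(codons[i], 3L, 3L) <- newBase
  list(nt = paste(codons, collapse = ""), n_swaps = length(flip))
}

# AT-rich random spacer sequence at the genome's target composition
randomSpacer <- function(len, targetGc) {
  p <- c(A = (1 - targetGc) / 2, C = targetGc / 2,
         G = targetGc / 2, T = (1 - targetGc) / 2)
  paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = "")
}

# rotate a Mitogenome so index r becomes index 0
rotateGenomeBy <- function(genome, r) {
  L <- nchar(genome@sequence)
  r <- r %% L
  if (r == 0L) return(genome)
  genome@sequence <- paste0(substr(genome@sequence, r + 1L, L),
                            substr(genome@sequence, 1L, r))
  f <- genome@features
  for (i in seq_len(nrow(f))) {
    ri <- rotateInterval(f$start[i], f$end[i], f$wraps_origin[i], r, L)
    f$start[i] <- ri$start; f$end[i] <- ri$end; f$wraps_origin[i] <- ri$wraps
  }
  genome@features <- f
  genome
}

#' Build a complete synthetic dataset with ground truth
#'
#' Generates, per species: a circular annotated genome assembled as
#' [gene][spacer][gene]... with 22 tRNA and 2 rRNA placeholder features in
#' the spacers and a random subset of genes on the minus strand; per gene:
#' a gap-free codon alignment of all species plus the 5-taxon synthetic
#' outgroup panel, every row evolved from a shared root; a trait table with
#' planted composition effects; a Newick guide tree; and machine-readable
#' ground-truth tables. Byte-reproducible for a fixed config.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param dir output directory (created).
#' @return invisible list: \code{paths} (genomes, alignment dir, traits,
#'   tree, truth files) and \code{truth} (list of data.frames:
#'   \code{rates}, \code{composition}, \code{traits}).
#' @export
buildDataset <- function(config, dir) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  alnDir <- file.path(dir, "alignments")
  if (!dir.exists(alnDir)) dir.create(alnDir)
  code <- geneticCode()
  genes <- names(config$geneCodons)
  nSp <- config$nSpecies
  speciesIds <- sprintf("SP%03d", seq_len(nSp))
  clade <- rep(config$clades, length.out = nSp)
  feeding <- rep(DEFAULT_FEEDING, length.out = nSp)
  habitat <- rep(DEFAULT_HABITAT, length.out = nSp)
  repro <- rep(DEFAULT_REPRODUCTION, length.out = nSp)

  set.seed(config$seed)
  # per-species planted 3rd-position skew deviation, in skew units
  shift <- unname(config$traitSkewShift[feeding])
  shift[is.na(shift)] <- 0
  deltaSkew3 <- config$skewSdUnit * (stats::rnorm(nSp) + shift)

  ff <- fourfoldCodons(code)
  roots <- stats::setNames(lapply(seq_along(genes), function(gi)
    sampleCodonSequence(config$geneCodons[[gi]], config$targetGc,
                        config$posSkews, code,
                        seed = deriveSeed(config$seed, gi))), genes)

  omegaSp <- unname(config$omegaByFeeding[feeding])
  omegaSp[is.na(omegaSp)] <- 0.2

  ratesTruth <- list(); seqs <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    for (si in seq_len(nSp)) {
      ev <- evolvePair(roots[[g]], config$tIngroup, omegaSp[si],
                       config$kappa, code,
                       seed = deriveSeed(config$seed, 1000L + gi * 100L + si))
      inj <- injectSkew(ev$nt, deltaSkew3[si], code, ff)
      seqs[[paste(speciesIds[si], g)]] <- inj$nt
      ratesTruth[[length(ratesTruth) + 1L]] <- data.frame(
        species_id = speciesIds[si], gene = g, t = config$tIngroup,
        omega_true = unname(omegaSp[si]),
        sd_true = ev$sd_true + inj$n_swaps, nd_true = ev$nd_true,
        n_codons = config$geneCodons[[gi]], stringsAsFactors = FALSE)
    }
    for (oi in seq_along(config$outgroupIds)) {
      ev <- evolvePair(roots[[g]], config$tOutgroup, config$omegaOutgroup,
                       config$kappa, code,
                       seed = deriveSeed(config$seed,
                                         500000L + gi * 100L + oi))
      seqs[[paste(config$outgroupIds[oi], g)]] <- ev$nt
      ratesTruth[[length(ratesTruth) + 1L]] <- data.frame(
        species_id = config$outgroupIds[oi], gene = g,
        t = config$tOutgroup, omega_true = config$omegaOutgroup,
        sd_true = ev$sd_true, nd_true = ev$nd_true,
        n_codons = config$geneCodons[[gi]], stringsAsFactors = FALSE)
    }
  }

  # per-gene alignment FASTAs (gap-free; all rows share the root length),
  # with the terminal stop codon appended as in the genomes
  taxa <- c(speciesIds, config$outgroupIds)
  for (g in genes) {
    rows <- stats::setNames(
      vapply(taxa, function(tx) paste0(seqs[[paste(tx, g)]], "TAA"),
             character(1)), taxa)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(rows),
                                file.path(alnDir, paste0(g, ".fasta")),
                                width = 70L)
  }

  # assemble circular annotated genomes
  gbPath <- file.path(dir, "genomes.gb")
  if (file.exists(gbPath)) file.remove(gbPath)
  trnaLen <- 60L; rrnaLens <- c(700L, 950L)
  genomes <- vector("list", nSp)
  for (si in seq_len(nSp)) {
    set.seed(deriveSeed(config$seed, 900000L + si))
    pieces <- character(0); feats <- list(); cursor <- 0L
    trnaLeft <- 22L; rrnaLeft <- 2L
    addFeat <- function(raw, norm, type, s, e, strand, off = 0L) {
      feats[[length(feats) + 1L]] <<- data.frame(
        raw_name = raw, norm_name = norm, type = type, start = s, end = e,
        strand = strand, frame_offset = off, wraps_origin = FALSE,
        stringsAsFactors = FALSE)
    }
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      cds <- paste0(seqs[[paste(speciesIds[si], g)]], "TAA")
      onMinus <- g %in% config$minusStrandGenes
      genomic <- if (onMinus) revComp(cds) else cds
      addFeat(g, g, "CDS", cursor, cursor + nchar(genomic),
              if (onMinus) "-" else "+")
      pieces <- c(pieces, genomic); cursor <- cursor + nchar(genomic)
      # spacer: intergenic padding with tRNA/rRNA placeholders
      nTrnaHere <- min(trnaLeft, if (gi %in% c(3L, 8L)) 1L else 2L)
      elems <- c(rep("pad", 1L), rep("trna", nTrnaHere),
                 if (gi %in% c(3L, 8L) && rrnaLeft > 0L) "rrna",
                 "pad")
      for (el in elems) {
        if (el == "pad") {
          len <- sample(30:80, 1L)
          pieces <- c(pieces, randomSpacer(len, config$targetGc))
          cursor <- cursor + len
        } else if (el == "trna") {
          s <- randomSpacer(trnaLen, config$targetGc)
          addFeat(sprintf("trn%d", 23L - trnaLeft), "TRNA", "tRNA",
                  cursor, cursor + trnaLen,
                  sample(c("+", "-"), 1L))
          pieces <- c(pieces, s); cursor <- cursor + trnaLen
          trnaLeft <- trnaLeft - 1L
        } else {
          len <- rrnaLens[3L - rrnaLeft]
          s <- randomSpacer(len, config$targetGc)
          addFeat(sprintf("rrn%s", if (rrnaLeft == 2L) "S" else "L"),
                  "RRNA", "rRNA", cursor, cursor + len, "+")
          pieces <- c(pieces, s); cursor <- cursor + len
          rrnaLeft <- rrnaLeft - 1L
        }
      }
    }
    genome <- new("Mitogenome", id = speciesIds[si],
                  sequence = paste(pieces, collapse = ""),
                  isCircular = TRUE,
                  features = do.call(rbind, feats),
                  taxonomy = character(0), traits = character(0))
    if (config$wrapOrigin) {
      f <- genome@features
      cox1 <- which(f$norm_name == "COX1")[1]
      mid <- f$start[cox1] + (f$end[cox1] - f$start[cox1]) %/% 2L
      genome <- rotateGenomeBy(genome, mid)
    }
    writeGenBank(genome, gbPath, append = si > 1L)
    genomes[[si]] <- genome
  }

  # trait table with a simple clade-consistent taxonomy scaffold
  traits <- data.frame(
    species_id = speciesIds,
    class = ifelse(clade == "Enoplea", "Enoplea", "Chromadorea"),
    subclass = ifelse(clade == "Enoplea", "Dorylaimia", "Chromadoria"),
    order = ifelse(clade == "Enoplea", "Dorylaimida", "Rhabditida"),
    suborder = ifelse(clade == "Enoplea", "Dorylaimina", clade),
    infraorder = paste0(clade, "_infra"),
    superfamily = paste0("Superfam_", rep(1:4, length.out = nSp)),
    family = paste0("Fam_", rep(1:7, length.out = nSp)),
    genus = paste0("Genus_", seq_len(nSp)),
    feeding_habit = feeding, habitat = habitat, reproduction = repro,
    stringsAsFactors = FALSE)
  traitPath <- file.path(dir, "traits.tsv")
  utils::write.table(traits, traitPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # guide tree: species clustered by clade (topology for display order)
  cladeGroups <- split(speciesIds, clade)
  nwk <- paste0("(", paste(vapply(cladeGroups, function(sp)
    if (length(sp) == 1L) sp else
      paste0("(", paste(sp, collapse = ","), ")"),
    character(1)), collapse = ","), ");")
  treePath <- file.path(dir, "guide_tree.nwk")
  ape::write.tree(ape::read.tree(text = nwk), treePath)

  ratesTruthDf <- do.call(rbind, ratesTruth)
  compTruth <- data.frame(
    species_id = speciesIds, target_gc = config$targetGc,
    target_skew1 = config$posSkews[1], target_skew2 = config$posSkews[2],
    target_skew3 = config$posSkews[3] + deltaSkew3,
    stringsAsFactors = FALSE)
  truthRatesPath <- file.path(dir, "truth_rates.tsv")
  truthCompPath <- file.path(dir, "truth_composition.tsv")
  utils::write.table(ratesTruthDf, truthRatesPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(compTruth, truthCompPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(
    paths = list(genomes = gbPath, alignments = alnDir,
                 traits = traitPath, tree = treePath,
                 truth_rates = truthRatesPath,
                 truth_composition = truthCompPath),
    truth = list(rates = ratesTruthDf, composition = compTruth,
                 traits = traits),
    genomes = genomes))
}
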