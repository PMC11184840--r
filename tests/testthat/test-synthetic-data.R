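# Synthetic-data generator: composition targeting, divergence simulation,
# dataset assembly, ground truth and determinism.

test_that("solved codon frequencies honor GC and per-position skew targets", {
  q <- solveCodonFrequencies(0.25, c(0.2, -0.1, 0.45))
  expect_equal(sum(q), 1)
  expect_false(any(c("TAA", "TAG") %in% names(q)))
  for (p in 1:3) {
    base <- substr(names(q), p, p)
    g <- sum(q[base == "G"]); cc <- sum(q[base == "C"])
    expect_equal((g - cc) / (g + cc), c(0.2, -0.1, 0.45)[p],
                 tolerance = 1e-3)
    expect_equal(g + cc, 0.25, tolerance = 1e-3)
  }
})

test_that("sampled codon sequences avoid stops and converge to targets", {
  nt <- sampleCodonSequence(10000, targetGc = 0.25,
                            posSkews = c(0, 0, 0.5), seed = 101)
  codons <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
  expect_false(any(codons %in% c("TAA", "TAG")))
  expect_true(abs(codonPositionSkew(nt, 3) - 0.5) <= 0.03)
  expect_true(abs(pctGc(nt) - 25) <= 1)

  flat <- sampleCodonSequence(10000, targetGc = 0.5,
                              posSkews = c(0, 0, 0), seed = 102)
  for (p in 1:3) expect_true(abs(codonPositionSkew(flat, p)) <= 0.03)

  tiny <- sampleCodonSequence(2, seed = 103)
  expect_identical(nchar(tiny), 6L)
  expect_error(sampleCodonSequence(1, seed = 1), ">= 2")
})

test_that("the evolver is the identity at t = 0 and obeys omega = 0", {
  anc <- sampleCodonSequence(100, seed = 111)
  ev0 <- evolvePair(anc, 0, 0.5, seed = 112)
  expect_identical(ev0$nt, anc)
  expect_identical(ev0$sd_true + ev0$nd_true, 0L)
  evS <- evolvePair(anc, 0.5, 0, seed = 113)
  expect_identical(evS$nd_true, 0L)
  # omega = 0 descendants stay protein-identical
  code <- geneticCode()
  aaA <- translateCodons(substring(anc, seq(1, 298, 3), seq(3, 300, 3)),
                         code)
  aaB <- translateCodons(substring(evS$nt, seq(1, 298, 3),
                                   seq(3, 300, 3)), code)
  expect_identical(aaA, aaB)
})

test_that("logged substitution events reconcile with observed differences", {
  anc <- sampleCodonSequence(2000, seed = 121)
  t <- divergenceTime(anc, 0.10, 0.5)
  ev <- evolvePair(anc, t, 0.5, seed = 122)
  obsDiffs <- sum(strsplit(anc, "")[[1]] != strsplit(ev$nt, "")[[1]])
  logged <- ev$sd_true + ev$nd_true
  # multiple hits make observed <= logged, but only slightly at ~10%
  expect_true(obsDiffs <= logged)
  expect_true(obsDiffs / logged > 0.85)
  # and the divergence calibration is close to its target
  expect_equal(obsDiffs / nchar(anc), 0.10, tolerance = 0.02)
  # counting estimator recovers the logged syn/nonsyn split approximately
  est <- ng86Pairwise(anc, ev$nt)
  expect_equal(est$Sd + est$Nd, obsDiffs, tolerance = 0.02)
  expect_equal(est$Sd / ev$sd_true, 1, tolerance = 0.2)
})

test_that("datasets assemble complete genomes with planted sequences", {
  dir <- tempfile()
  cfg <- syntheticConfig(nSpecies = 5, seed = 131,
                         geneCodons = DEFAULT_TEST_GENES)
  d <- buildDataset(cfg, dir)
  genomes <- readGenBank(file.path(dir, "genomes.gb"))
  expect_length(genomes, 5L)
  comp <- do.call(rbind, lapply(genomes, completenessReport))
  expect_true(all(comp$n_pcgs == 12L))
  expect_true(all(comp$n_trnas == 22L))
  expect_true(all(comp$n_rrnas == 2L))
  expect_true(all(comp$is_complete))
  # extraction reproduces the alignment rows (the planted sequences)
  for (g in genomes[1:2]) {
    cdss <- extractPcgs(g)
    for (gene in c("COX1", "NAD5", "ATP6")) {
      aln <- readAlignment(file.path(dir, "alignments",
                                     paste0(gene, ".fasta")))
      expect_identical(codingNt(cdss[[gene]]),
                       unname(alignedSeqs(aln)[genomeId(g)]))
    }
  }
  # trait table and tree cover all species
  traits <- readTraitTable(d$paths$traits)
  expect_setequal(rownames(traits), vapply(genomes, genomeId, character(1)))
  tree <- ape::read.tree(d$paths$tree)
  expect_setequal(tree$tip.label, rownames(traits))
  # truth tables are internally consistent with the config
  expect_true(all(d$truth$rates$t %in% c(cfg$tIngroup, cfg$tOutgroup)))
})

test_that("identical configs give byte-identical datasets", {
  cfg1 <- syntheticConfig(nSpecies = 4, seed = 141,
                          geneCodons = c(COX1 = 40L, NAD2 = 30L,
                                         ATP6 = 25L))
  cfg2 <- syntheticConfig(nSpecies = 4, seed = 141,
                          geneCodons = c(COX1 = 40L, NAD2 = 30L,
                                         ATP6 = 25L))
  d1 <- tempfile(); d2 <- tempfile()
  buildDataset(cfg1, d1); buildDataset(cfg2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("a full-length genome recovers the planted composition targets", {
  cfg <- syntheticConfig(nSpecies = 1, seed = 151)
  dir <- tempfile()
  buildDataset(cfg, dir)
  g <- readGenBank(file.path(dir, "genomes.gb"))[[1]]
  rec <- genomeSummary(g)
  expect_equal(rec$summary$genome_pct_gc, 25, tolerance = 1)
  expect_equal(rec$summary$pcg_pct_gc, 25, tolerance = 1)
  # genome shape approximates the study panel: ~14.5 kb, ~70% coding
  expect_true(abs(rec$summary$genome_length - 14500) < 1000)
  expect_true(abs(rec$summary$pcg_proportion - 0.70) < 0.05)
})

test_that("trait-shifted species carry lower third-position skews", {
  cfg <- syntheticConfig(nSpecies = 12, seed = 161,
                         geneCodons = c(COX1 = 300L, NAD4 = 250L,
                                        NAD5 = 300L, ATP6 = 150L))
  dir <- tempfile()
  d <- buildDataset(cfg, dir)
  comp <- d$truth$composition
  traits <- d$truth$traits
  para <- comp$target_skew3[traits$feeding_habit == "animal_parasite"]
  rest <- comp$target_skew3[traits$feeding_habit != "animal_parasite"]
  expect_true(mean(para) < mean(rest))
  # realized skews track the per-species targets (root sampling noise at
  # ~1,000 codons gives a per-species se of ~0.06 on the skew)
  genomes <- readGenBank(file.path(dir, "genomes.gb"))
  realized <- vapply(genomes, function(g) {
    pcg <- paste(vapply(extractPcgs(g), codingNt, character(1)),
                 collapse = "")
    codonPositionSkew(pcg, 3)
  }, numeric(1))
  target <- comp$target_skew3[match(vapply(genomes, genomeId,
                                           character(1)),
                                    comp$species_id)]
  expect_true(mean(abs(realized - target)) < 0.08)
  isPara <- traits$feeding_habit == "animal_parasite"
  expect_true(mean(realized[isPara]) < mean(realized[!isPara]))
})
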