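# NG86-type site/difference counting, pairwise estimates and outgroup
# averaging.

test_that("site counts match known table-5 degeneracies", {
  s <- countSites("TTT")
  expect_equal(s[["s"]], 1 / 3)   # only TTT->TTC synonymous
  expect_equal(s[["n"]], 8 / 3)
  # fourfold-degenerate family: position 3 contributes a full site
  gga <- countSites("GGA")
  expect_true(gga[["s"]] >= 1)
  expect_equal(sum(countSites("ATG")), 3)  # conservation
  expect_error(countSites("TAA"), "stop")
  expect_error(countSites("ANG"), "codon")
})

test_that("difference counting follows stop-free minimal paths", {
  expect_equal(unname(countDifferences("TTT", "TTT")[1:2]), c(0, 0))
  d <- countDifferences("TTT", "TTA")   # Phe -> Leu
  expect_equal(d[["sd"]], 0)
  expect_equal(d[["nd"]], 1)
  # two-difference pair against the recursive path-enumeration oracle
  d2 <- countDifferences("TTT", "GTA")
  o2 <- oracleDiffs("TTT", "GTA")
  expect_equal(d2[["sd"]], o2[["sd"]])
  expect_equal(d2[["nd"]], o2[["nd"]])
  expect_equal(d2[["sd"]] + d2[["nd"]], 2)
})

test_that("stop-obstructed pairs fall back to flagged all-path classification", {
  # TTA <-> CAA: intermediates TAA (stop) and CTA; one stop-free path remains
  d <- countDifferences("TTA", "CAA")
  expect_false(attr(d, "stop_path"))
  expect_equal(d[["sd"]] + d[["nd"]], 2)
  o <- oracleDiffs("TTA", "CAA")
  expect_equal(d[["sd"]], o[["sd"]])
})

test_that("pairwise estimates behave at the boundaries", {
  set.seed(2)
  nt <- paste(sample(ORACLE_SENSE, 60, TRUE), collapse = "")
  same <- ng86Pairwise(nt, nt)
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  expect_identical(same$status, "ok")

  short <- ng86Pairwise(strrep("ATT", 10), strrep("ATT", 10))
  expect_identical(short$status, "insufficient_sites")

  # all-synonymous saturation: every codon differs synonymously at a
  # fourfold third position, driving pS over the correction boundary
  a <- strrep("GGA", 40); b <- strrep("GGC", 40)
  sat <- ng86Pairwise(a, b)
  expect_true(sat$pS >= 0.75)
  expect_identical(sat$status, "saturated_dS")
  expect_true(is.na(sat$omega))
})

test_that("pairwise estimation is symmetric and masks pairwise", {
  set.seed(9)
  anc <- sampleCodonSequence(300, seed = 14)
  ev <- evolvePair(anc, 0.2, 0.5, seed = 15)
  ab <- ng86Pairwise(anc, ev$nt)
  ba <- ng86Pairwise(ev$nt, anc)
  expect_equal(ab[, c("S_sites", "N_sites", "Sd", "Nd", "dS", "dN")],
               ba[, c("S_sites", "N_sites", "Sd", "Nd", "dS", "dN")])
  # codons with gaps or stops in either row are masked for the pair
  a2 <- paste0("TAA", "---", substr(anc, 7, nchar(anc)))
  m <- ng86Pairwise(a2, ev$nt)
  expect_equal(m$n_codons_compared, 300 - 2)
})

test_that("synonymous-only divergence gives dS > 0 with dN = 0", {
  anc <- sampleCodonSequence(500, seed = 21)
  ev <- evolvePair(anc, 0.08, omega = 0, seed = 22)
  expect_identical(ev$nd_true, 0L)
  est <- ng86Pairwise(anc, ev$nt)
  expect_equal(est$dN, 0)
  expect_true(est$dS > 0)
})

test_that("Jukes-Cantor correction linearizes at small divergence", {
  anc <- sampleCodonSequence(2000, seed = 41)
  ev <- evolvePair(anc, 0.005, 0.5, seed = 42)
  est <- ng86Pairwise(anc, ev$nt)
  expect_true(est$pS <= 0.02)
  expect_true(abs(est$dS - est$pS) <= 1e-4)
  expect_true(abs(est$dN - est$pN) <= 1e-4)
})

test_that("outgroup averaging skips non-ok pairs and records coverage", {
  anc <- sampleCodonSequence(200, seed = 51)
  ogs <- c(og1 = evolvePair(anc, 0.1, 0.3, seed = 52)$nt,
           og2 = evolvePair(anc, 0.1, 0.3, seed = 53)$nt,
           og3 = strrep("GGA", 200))  # saturated partner for a GGC repeat?
  # make the third outgroup unusable: too few comparable codons
  ogs[["og3"]] <- paste(rep("---", 200), collapse = "")
  avg <- averageOverOutgroups(anc, ogs, speciesId = "sp", gene = "COX1")
  expect_identical(avg$n_outgroups_used, 2L)
  est1 <- ng86Pairwise(anc, ogs[["og1"]])
  est2 <- ng86Pairwise(anc, ogs[["og2"]])
  expect_equal(avg$dN_mean, mean(c(est1$dN, est2$dN)))
  expect_equal(avg$dS_mean, mean(c(est1$dS, est2$dS)))
  # ratio of means, not mean of ratios
  expect_equal(avg$omega, avg$dN_mean / avg$dS_mean)

  none <- averageOverOutgroups(anc,
                               c(og = paste(rep("---", 200), collapse = "")))
  expect_true(none$missing)
  expect_true(is.na(none$dN_mean))
})

test_that("rates tables cover species x gene with planted missingness", {
  b1 <- makeBlock(c(sp1 = strrep("ATTGGATGT", 20),
                    sp2 = strrep("ATTGGGTGT", 20),
                    og1 = strrep("ATTGGCTGT", 20),
                    og2 = strrep("ATCGGATGT", 20)), gene = "COX1")
  # sp2 has every codon gapped in NAD2 -> missing there
  b2 <- makeBlock(c(sp1 = strrep("TGTCATAAG", 20),
                    sp2 = paste(rep("---------", 20), collapse = ""),
                    og1 = strrep("TGTCACAAG", 20),
                    og2 = strrep("TGCCATAAG", 20)), gene = "NAD2")
  tab <- ratesTable(list(b1, b2), outgroupIds = c("og1", "og2"))
  expect_identical(nrow(tab), 4L)  # 2 species x 2 genes
  expect_true(tab$missing[tab$species_id == "sp2" & tab$gene == "NAD2"])
  expect_false(any(tab$missing[tab$gene == "COX1"]))
  # identical rows give zero distances
  bEq <- makeBlock(c(sp1 = strrep("ATTGGA", 30), og1 = strrep("ATTGGA", 30)),
                   gene = "ATP6")
  tEq <- ratesTable(list(bEq), outgroupIds = "og1")
  expect_equal(tEq$dN_mean, 0)
  expect_equal(tEq$dS_mean, 0)
})
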