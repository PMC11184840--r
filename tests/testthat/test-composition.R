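# Composition metrics: skews, %GC, codon-position partitioning, genome and
# clade summaries.

test_that("skew and %GC formulas match direct counting", {
  expect_equal(gcSkew("GGGC"), 0.5)
  expect_true(is.na(gcSkew("ATATAT")))
  expect_equal(atSkew("AAT"), 1 / 3)
  expect_true(is.na(atSkew("GC")))
  expect_equal(pctGc("GCGC"), 100)
  expect_equal(pctGc("ATGC"), 50)
  expect_equal(pctGc("ATGCN"), 50)  # ambiguity excluded
  expect_true(is.na(pctGc("NNN")))
})

test_that("skews are antisymmetric under complementation and bounded", {
  set.seed(31)
  for (i in 1:50) {
    s <- randomDna(sample(50:400, 1))
    rc <- revComp(s)
    expect_equal(gcSkew(rc), -gcSkew(s))
    expect_equal(atSkew(rc), -atSkew(s))
    expect_true(abs(gcSkew(s)) <= 1)
    expect_true(abs(atSkew(s)) <= 1)
    # sequence + its complement is balanced (or undefined)
    both <- paste0(s, rc)
    expect_true(is.na(gcSkew(both)) || abs(gcSkew(both)) < 1e-12)
  }
})

test_that("codon-position skews partition the coding sequence", {
  expect_equal(codonPositionSkew("GATGCTGGT", 1), 1)   # G,G,G
  expect_true(is.na(codonPositionSkew("GATGCTGGT", 3)))  # T,T,T
  expect_error(codonPositionSkew("GATGCTGGT", 4), "position")
  set.seed(7)
  for (i in 1:20) {
    nt <- randomDna(3 * sample(10:100, 1))
    subs <- vapply(1:3, function(p) {
      idx <- seq.int(p, nchar(nt), 3)
      paste(substring(nt, idx, idx), collapse = "")
    }, character(1))
    # multiset union of the three position subsequences equals the cds
    expect_identical(sort(strsplit(paste(subs, collapse = ""), "")[[1]]),
                     sort(strsplit(nt, "")[[1]]))
    expect_identical(sum(nchar(subs)), nchar(nt))
  }
})

test_that("genome summaries populate all resolutions consistently", {
  g <- makeTestGenome(list(COX1 = list(nt = strrep("ATTGGA", 40),
                                       strand = "+"),
                           NAD2 = list(nt = strrep("GGTTAT", 20),
                                       strand = "-")),
                      spacer = strrep("AT", 50))
  rec <- genomeSummary(g)
  s <- rec$summary
  expect_equal(s$pcg_total_length, 240 + 120)
  expect_equal(s$pcg_proportion, 360 / nchar(genomeSequence(g)))
  expect_identical(nrow(rec$perGene), 2L)
  expect_identical(nrow(rec$perCodonPosition), 6L)
  expect_equal(sum(rec$perGene$length), s$pcg_total_length)
  # per-gene metrics are on the coding strand
  expect_equal(rec$perGene$gc_skew[rec$perGene$gene == "NAD2"],
               gcSkew(strrep("GGTTAT", 20)))
})

test_that("degenerate all-A genome gives zero GC and undefined skew", {
  g <- makeTestGenome(list(NAD1 = list(nt = strrep("AAA", 10),
                                       strand = "+")),
                      spacer = strrep("A", 20))
  rec <- genomeSummary(g)
  expect_equal(rec$summary$genome_pct_gc, 0)
  expect_true(is.na(rec$summary$genome_gc_skew))
})

test_that("genome summary requires at least one PCG", {
  g <- makeTestGenome(list(NAD1 = list(nt = "ATTATT", strand = "+")))
  g@features <- g@features[0, ]
  expect_error(genomeSummary(g, list()), "zero")
})

test_that("clade summaries match an independent accumulation", {
  two <- data.frame(species_id = c("a", "b"),
                    genome_length = c(12000, 14000))
  cs <- cladeSummary(two, c(a = "g1", b = "g1"))
  expect_equal(cs$mean[cs$metric == "genome_length"], 13000)
  expect_equal(cs$sd[cs$metric == "genome_length"], 1414.2, tolerance = 1e-4)

  single <- cladeSummary(two[1, , drop = FALSE], c(a = "g1"))
  expect_true(is.na(single$sd[1]))

  set.seed(11)
  n <- 50
  tab <- data.frame(species_id = sprintf("s%02d", 1:n),
                    m1 = rnorm(n), m2 = c(rnorm(n - 5), rep(NA, 5)))
  grp <- setNames(sample(c("x", "y", "z"), n, TRUE), tab$species_id)
  cs <- cladeSummary(tab, grp)
  for (g in c("x", "y", "z")) {
    for (m in c("m1", "m2")) {
      v <- tab[[m]][grp[tab$species_id] == g]
      v <- v[!is.na(v)]
      row <- cs[cs$group == g & cs$metric == m, ]
      expect_identical(row$n, length(v))
      expect_equal(row$mean, mean(v))
      expect_equal(row$sd, sd(v))
      expect_equal(row$min, min(v))
      expect_equal(row$max, max(v))
    }
  }
})

test_that("composition metrics are invariant under COX1 rotation", {
  set.seed(21)
  cox1 <- paste(sample(ORACLE_SENSE, 60, TRUE), collapse = "")
  nad4 <- paste(sample(ORACLE_SENSE, 40, TRUE), collapse = "")
  g <- makeTestGenome(list(COX1 = list(nt = cox1, strand = "+"),
                           NAD4 = list(nt = nad4, strand = "+")),
                      spacer = randomDna(200))
  o <- orientToCox1(g)
  a <- genomeSummary(g); b <- genomeSummary(o)
  expect_equal(a$summary[, -1], b$summary[, -1])
  expect_equal(a$perGene[, -1], b$perGene[, -1])
  expect_equal(a$perCodonPosition[, -1], b$perCodonPosition[, -1])
})

test_that("composition tables write in tree order with heatmap matrix", {
  g1 <- makeTestGenome(list(COX1 = list(nt = strrep("ATTGGA", 10),
                                        strand = "+")), id = "spA")
  g2 <- makeTestGenome(list(COX1 = list(nt = strrep("GGTTAT", 10),
                                        strand = "+")), id = "spB")
  tables <- compositionTable(list(genomeSummary(g1), genomeSummary(g2)))
  dir <- tempfile(); dir.create(dir)
  nwk <- tempfile(fileext = ".nwk")
  writeLines("(spB,spA);", nwk)
  writeCompositionTables(tables, dir, treePath = nwk)
  wide <- read.delim(file.path(dir, "codon_position_gc_skew.tsv"))
  expect_identical(wide$species_id, c("spB", "spA"))
  expect_true("COX1.pos1" %in% names(wide))
})
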