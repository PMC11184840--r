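# GenBank parsing, gene-name normalization, PCG extraction, COX1
# orientation and trait-table I/O.

test_that("GenBank records parse with coordinate conversion and wrapping joins", {
  L <- 300L
  seq <- randomDna(L)
  gb <- tempfile(fileext = ".gb")
  genome <- methods::new("Mitogenome", id = "REC1", sequence = seq,
                         isCircular = TRUE,
                         features = data.frame(
                           raw_name = c("COI", "ND2", "trnK", "rrnS"),
                           norm_name = c("COX1", "NAD2", "TRNA", "RRNA"),
                           type = c("CDS", "CDS", "tRNA", "rRNA"),
                           start = c(250L, 30L, 100L, 130L),
                           end = c(50L, 90L, 120L, 160L),
                           strand = c("+", "-", "+", "+"),
                           frame_offset = c(0L, 1L, 0L, 0L),
                           wraps_origin = c(TRUE, FALSE, FALSE, FALSE),
                           stringsAsFactors = FALSE),
                         taxonomy = character(0), traits = character(0))
  writeGenBank(genome, gb)
  parsed <- readGenBank(gb)
  expect_length(parsed, 1L)
  p <- parsed[[1]]
  expect_identical(genomeId(p), "REC1")
  expect_identical(genomeSequence(p), seq)
  expect_true(p@isCircular)
  f <- genomeFeatures(p)
  cox1 <- f[f$norm_name == "COX1", ]
  expect_true(cox1$wraps_origin)
  expect_identical(cox1$start, 250L)
  expect_identical(cox1$end, 50L)
  # wrapped slice length = (L - start) + end
  expect_identical((L - cox1$start) + cox1$end, 100L)
  nad2 <- f[f$norm_name == "NAD2", ]
  expect_identical(nad2$strand, "-")
  expect_identical(nad2$frame_offset, 1L)
  expect_identical(sum(f$type == "tRNA"), 1L)
})

test_that("raw annotation names map onto canonical PCG names", {
  expect_identical(normalizeGeneName("COI"), "COX1")
  expect_identical(normalizeGeneName("ND4L"), "NAD4L")
  expect_identical(normalizeGeneName("CYTB"), "CYTB")
  expect_identical(normalizeGeneName("cob"), "CYTB")
  expect_identical(normalizeGeneName("ATPase6"), "ATP6")
  expect_identical(normalizeGeneName("cytochrome c oxidase subunit I"),
                   "COX1")
  expect_identical(normalizeGeneName("hypothetical protein"), "OTHER")
  expect_identical(normalizeGeneName(c("nd1", "Cox-2")), c("NAD1", "COX2"))
  expect_identical(normalizeGeneName("mygene", extra = c(mygene = "NAD3")),
                   "NAD3")
})

test_that("empty GenBank file yields an empty genome list", {
  f <- tempfile()
  writeLines(character(0), f)
  expect_identical(readGenBank(f), list())
})

test_that("missing sequence in a record is an error naming the record", {
  f <- tempfile()
  writeLines(c("LOCUS       BAD1   100 bp DNA circular",
               "FEATURES             Location/Qualifiers", "//"), f)
  expect_error(readGenBank(f), "BAD1")
})

test_that("PCG extraction handles strand, frame and truncation", {
  # minus-strand gene whose genomic slice is TTACATTGA
  g <- makeTestGenome(list(NAD3 = list(nt = revComp("TTACATTGA"),
                                       strand = "-")))
  cds <- extractPcgs(g)$NAD3
  expect_identical(codingNt(cds), "TCAATGTAA")
  expect_identical(cds@nCodons, 3L)
  expect_false(cds@hasInternalStop)
  expect_identical(cds@sourceStrand, "-")

  # internal TAA at codon 2 of 3
  g2 <- makeTestGenome(list(NAD3 = list(nt = "ATTTAAATT", strand = "+")))
  expect_true(extractPcgs(g2)$NAD3@hasInternalStop)

  # trailing partial codon truncated: 10 nt -> 3 codons
  g3 <- makeTestGenome(list(NAD3 = list(nt = "ATTATTATTA", strand = "+")))
  expect_identical(extractPcgs(g3)$NAD3@nCodons, 3L)
  expect_identical(nchar(codingNt(extractPcgs(g3)$NAD3)), 9L)

  # frame offset drops lead-in bases
  g4 <- makeTestGenome(list(NAD3 = list(nt = "GATTATTATT", strand = "+",
                                        offset = 1L)))
  expect_identical(codingNt(extractPcgs(g4)$NAD3), "ATTATTATT")
})

test_that("duplicate PCG annotations are rejected with both features named", {
  g <- makeTestGenome(list(NAD3 = list(nt = "ATTATTATT", strand = "+")))
  f <- g@features
  f2 <- f[1, ]; f2$raw_name <- "nd3"
  g@features <- rbind(f, f2)
  expect_error(extractPcgs(g), "NAD3")
})

test_that("COX1 orientation rotates coordinates and is idempotent", {
  cox1 <- paste(rep("ATTGGA", 20), collapse = "")
  nad2 <- paste(rep("GGTTAT", 10), collapse = "")
  g <- makeTestGenome(list(COX1 = list(nt = cox1, strand = "+"),
                           NAD2 = list(nt = nad2, strand = "+")),
                      spacer = strrep("AT", 25))
  o <- orientToCox1(g)
  f <- genomeFeatures(o)
  expect_identical(f$start[f$norm_name == "COX1"], 0L)
  expect_identical(f$end[f$norm_name == "COX1"], nchar(cox1))
  # composition is invariant under rotation
  expect_identical(gcSkew(genomeSequence(o)), gcSkew(genomeSequence(g)))
  expect_identical(pctGc(genomeSequence(o)), pctGc(genomeSequence(g)))
  # extracted coding sequences are unchanged by orientation
  expect_identical(codingNt(extractPcgs(o)$NAD2),
                   codingNt(extractPcgs(g)$NAD2))
  # idempotence
  o2 <- orientToCox1(o)
  expect_identical(genomeSequence(o2), genomeSequence(o))
  expect_identical(genomeFeatures(o2), genomeFeatures(o))
})

test_that("minus-strand COX1 flips the molecule; %GC preserved, skew negated", {
  set.seed(4)
  cox1 <- paste(sample(c("ATT", "GGA", "TGT", "CAT"), 40, TRUE),
                collapse = "")
  g <- makeTestGenome(list(COX1 = list(nt = cox1, strand = "-"),
                           NAD1 = list(nt = "ATTGGAATT", strand = "+")),
                      spacer = "ACGTACGTAA")
  o <- orientToCox1(g)
  f <- genomeFeatures(o)
  expect_identical(f$strand[f$norm_name == "COX1"], "+")
  expect_identical(f$start[f$norm_name == "COX1"], 0L)
  expect_equal(pctGc(genomeSequence(o)), pctGc(genomeSequence(g)))
  expect_equal(gcSkew(genomeSequence(o)), -gcSkew(genomeSequence(g)))
  expect_identical(codingNt(extractPcgs(o)$COX1),
                   codingNt(extractPcgs(g)$COX1))
})

test_that("orientation refuses non-circular genomes and genomes without COX1", {
  g <- makeTestGenome(list(NAD1 = list(nt = "ATTGGAATT", strand = "+")))
  expect_error(orientToCox1(g), "COX1")
  g2 <- makeTestGenome(list(COX1 = list(nt = "ATTGGAATT", strand = "+")),
                       circular = FALSE)
  expect_error(orientToCox1(g2), "circular")
})

test_that("trait tables round-trip with missing markers and validation", {
  tab <- rbind(baseTraitRow("sp1", feeding = "animal_parasite"),
               baseTraitRow("sp2"), baseTraitRow("sp3"))
  tab$habitat[2] <- "NA"; tab$reproduction[3] <- ""
  path <- writeTraitTsv(tab, tempfile(fileext = ".tsv"))
  tt <- readTraitTable(path)
  expect_identical(nrow(tt), 3L)
  expect_identical(tt["sp1", "feeding_habit"], "animal_parasite")
  expect_true(is.na(tt["sp2", "habitat"]))
  expect_true(is.na(tt["sp3", "reproduction"]))

  dup <- rbind(tab, baseTraitRow("sp1"))
  expect_error(readTraitTable(writeTraitTsv(dup, tempfile())), "sp1")
  nocol <- tab[, setdiff(names(tab), "habitat")]
  expect_error(readTraitTable(writeTraitTsv(nocol, tempfile())), "habitat")
})

test_that("coding sequences written to FASTA re-read identically", {
  g <- makeTestGenome(list(COX1 = list(nt = "ATTGGAACTTAT", strand = "+"),
                           NAD5 = list(nt = "TGTCATAAGTAA", strand = "-")))
  cdss <- extractPcgs(g)
  dir <- tempfile(); dir.create(dir)
  writeCodingFasta(cdss, dir)
  for (nm in names(cdss)) {
    back <- Biostrings::readDNAStringSet(file.path(dir,
                                                   paste0(nm, ".fasta")))
    expect_identical(unname(as.character(back)), codingNt(cdss[[nm]]))
  }
})
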