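# Independent oracles and fixture builders. These deliberately avoid the
# package's own GeneticCode machinery and path/permutation code so they can
# serve as cross-checks.

ORACLE_MAP <- Biostrings::getGeneticCode("5")
ORACLE_BASES <- c("A", "C", "G", "T")
ORACLE_SENSE <- names(ORACLE_MAP)[ORACLE_MAP != "*"]

oracleIsStop <- function(cd) unname(ORACLE_MAP[cd]) == "*"

# site counts by direct neighbor enumeration
oracleSites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; denom <- 0
    for (b in ORACLE_BASES[ORACLE_BASES != ch[pos]]) {
      nb <- ch; nb[pos] <- b
      ncd <- paste(nb, collapse = "")
      if (oracleIsStop(ncd)) next
      denom <- denom + 1
      if (ORACLE_MAP[[ncd]] == ORACLE_MAP[[codon]]) syn <- syn + 1
    }
    if (denom > 0) s <- s + syn / denom
  }
  c(s = s, n = 3 - s)
}

# difference classification by recursive enumeration of every complete
# mutational path (depth-first), averaging over stop-free paths; falls back
# to all paths when none is stop-free
oracleDiffs <- function(a, b, allowStops = FALSE) {
  recurse <- function(cur) {
    dp <- which(strsplit(cur, "")[[1]] != strsplit(b, "")[[1]])
    if (!length(dp)) return(list(c(0, 0)))
    paths <- list()
    for (pos in dp) {
      ch <- strsplit(cur, "")[[1]]
      ch[pos] <- strsplit(b, "")[[1]][pos]
      nxt <- paste(ch, collapse = "")
      if (!allowStops && oracleIsStop(nxt)) next
      step <- if (ORACLE_MAP[[cur]] == ORACLE_MAP[[nxt]] &&
                  ORACLE_MAP[[cur]] != "*") c(1, 0) else c(0, 1)
      for (tail in recurse(nxt)) {
        paths[[length(paths) + 1]] <- step + tail
      }
    }
    paths
  }
  paths <- recurse(a)
  if (!length(paths)) return(oracleDiffs(a, b, allowStops = TRUE))
  avg <- Reduce(`+`, paths) / length(paths)
  c(sd = avg[1], nd = avg[2])
}

# hand-built Mitogenome: genes = named list with fields nt (coding-strand
# sequence as it should be extracted), strand, and optional frame lead-in
makeTestGenome <- function(genes, id = "test", spacer = "ATATAT",
                           circular = TRUE) {
  pieces <- character(0); feats <- list(); cursor <- 0L
  addPiece <- function(p) {
    pieces <<- c(pieces, p); cursor <<- cursor + nchar(p)
  }
  addPiece(spacer)
  for (nm in names(genes)) {
    g <- genes[[nm]]
    genomic <- if (g$strand == "-") mitocompare::revComp(g$nt) else g$nt
    feats[[length(feats) + 1L]] <- data.frame(
      raw_name = nm, norm_name = mitocompare::normalizeGeneName(nm),
      type = "CDS", start = cursor, end = cursor + nchar(genomic),
      strand = g$strand, frame_offset = g$offset %||% 0L,
      wraps_origin = FALSE, stringsAsFactors = FALSE)
    addPiece(genomic)
    addPiece(spacer)
  }
  methods::new("Mitogenome", id = id,
               sequence = paste(pieces, collapse = ""),
               isCircular = circular, features = do.call(rbind, feats),
               taxonomy = character(0), traits = character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

randomDna <- function(n) paste(sample(ORACLE_BASES, n, replace = TRUE),
                               collapse = "")

# small aligned block built directly
makeBlock <- function(seqs, gene = "TEST") {
  w <- nchar(seqs[[1]])
  methods::new("AlignmentBlock", gene = gene, seqs = seqs,
               codonPositionOfColumn = rep(1:3, length.out = w),
               geneOfColumn = rep(gene, w),
               allGap = stats::setNames(logical(length(seqs)), names(seqs)))
}

writeTraitTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

baseTraitRow <- function(id, feeding = "bacterivore",
                         habitat = "terrestrial", repro = "amphimictic") {
  data.frame(species_id = id, class = "Chromadorea",
             subclass = "Chromadoria", order = "Rhabditida",
             suborder = "Rhabditina", infraorder = "Rhabditomorpha",
             superfamily = "S1", family = "F1",
             genus = paste0("G_", id), feeding_habit = feeding,
             habitat = habitat, reproduction = repro,
             stringsAsFactors = FALSE)
}

# reduced 12-gene scheme for fast dataset-level tests
DEFAULT_TEST_GENES <- c(COX1 = 80L, COX2 = 60L, COX3 = 60L, CYTB = 70L,
                        NAD1 = 60L, NAD2 = 60L, NAD3 = 40L, NAD4 = 70L,
                        NAD4L = 30L, NAD5 = 80L, NAD6 = 40L, ATP6 = 50L)
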