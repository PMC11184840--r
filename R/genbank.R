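# GenBank flat-file reader and writer.
#
# Coordinates are converted at this boundary: GenBank 1-based inclusive
# locations become 0-based half-open [start, end) internally. A CDS
# annotated join(a..L, 1..b) on a circular molecule is flagged
# wraps_origin with start = a-1, end = b.

parseLocation <- function(loc, genomeLength, recordId) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    body <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(body, ",", fixed = TRUE)[[1]]
  } else {
    parts <- loc
  }
  seg <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) == 3L) return(as.integer(m[2:3]))
    if (grepl("^\\d+$", p)) return(rep(as.integer(p), 2L))
    stop("malformed location '", p, "' in record ", recordId)
  })
  if (length(seg) == 1L) {
    s <- seg[[1]]
    list(start = s[1] - 1L, end = s[2], wraps = FALSE, strand = strand)
  } else if (length(seg) == 2L &&
             seg[[1]][2] == genomeLength && seg[[2]][1] == 1L) {
    # join across the origin of the circular molecule
    list(start = seg[[1]][1] - 1L, end = seg[[2]][2], wraps = TRUE,
         strand = strand)
  } else {
    stop("unsupported multi-segment location in record ", recordId,
         ": ", loc)
  }
}

parseOneRecord <- function(lines) {
  locusLine <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locusLine)) stop("GenBank record without LOCUS line")
  toks <- strsplit(trimws(locusLine[1]), "[[:space:]]+")[[1]]
  recId <- toks[2]
  lenTok <- suppressWarnings(as.integer(toks[3]))
  circular <- any(grepl("circular", locusLine[1], ignore.case = TRUE))
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(acc[1]), "[[:space:]]+")[[1]]
    if (length(a) >= 2L) recId <- a[2]
  }

  oi <- grep("^ORIGIN", lines)
  if (!length(oi))
    stop("record ", recId, ": sequence (ORIGIN section) absent")
  seqLines <- lines[(oi[1] + 1L):length(lines)]
  seqLines <- seqLines[!grepl("^//", seqLines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (nchar(sequence) == 0L)
    stop("record ", recId, ": sequence absent")
  if (!is.na(lenTok) && lenTok != nchar(sequence))
    stop("record ", recId, ": LOCUS length ", lenTok,
         " does not match sequence length ", nchar(sequence))
  L <- nchar(sequence)

  fi <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fi)) {
    fl <- lines[(fi[1] + 1L):(oi[1] - 1L)]
    # group physical lines into features: a new feature starts where a key
    # appears at column 6 (5 leading spaces, then non-space)
    starts <- grep("^ {5}[^ ]", fl)
    for (k in seq_along(starts)) {
      blockEnd <- if (k < length(starts)) starts[k + 1L] - 1L else length(fl)
      block <- fl[starts[k]:blockEnd]
      head1 <- trimws(block[1])
      key <- sub("[[:space:]].*$", "", head1)
      rest <- trimws(sub("^[^[:space:]]+[[:space:]]+", "", head1))
      # location may continue on lines not starting with '/'
      qualStart <- grep("^[[:space:]]*/", block)
      locEnd <- if (length(qualStart)) qualStart[1] - 1L else length(block)
      locStr <- paste(c(rest, trimws(block[seq_len(locEnd)[-1]])),
                      collapse = "")
      quals <- trimws(block[grepl("^[[:space:]]*/", block)])
      getQual <- function(name) {
        hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub("^\"|\"$", "", sub(paste0("^/", name, "="), "", hit[1]))
      }
      if (!key %in% c("CDS", "tRNA", "rRNA")) next
      pl <- parseLocation(locStr, L, recId)
      gene <- getQual("gene")
      if (is.na(gene)) gene <- getQual("product")
      if (is.na(gene)) gene <- ""
      cs <- getQual("codon_start")
      frameOffset <- if (is.na(cs)) 0L else as.integer(cs) - 1L
      feats[[length(feats) + 1L]] <- data.frame(
        raw_name = gene,
        norm_name = if (key == "CDS") normalizeGeneName(gene)
                    else if (key == "tRNA") "TRNA" else "RRNA",
        type = key,
        start = pl$start, end = pl$end, strand = pl$strand,
        frame_offset = frameOffset, wraps_origin = pl$wraps,
        stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(raw_name = character(), norm_name = character(),
               type = character(), start = integer(), end = integer(),
               strand = character(), frame_offset = integer(),
               wraps_origin = logical(), stringsAsFactors = FALSE)

  new("Mitogenome", id = recId, sequence = sequence,
      isCircular = circular, features = features,
      taxonomy = character(0), traits = character(0))
}

#' Read annotated mitogenomes from a GenBank flat file
#'
#' Parses one or more GenBank records (CDS/tRNA/rRNA features, with
#' \code{join} and \code{complement} locations) into
#' \code{\linkS4class{Mitogenome}} objects. Gene names are normalized via
#' \code{\link{normalizeGeneName}}; origin-spanning joins are flagged.
#'
#' @param path path to a GenBank flat file (may contain multiple records).
#' @return list of \code{Mitogenome} objects (empty list for an empty file).
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) return(list())
  recStarts <- grep("^LOCUS", lines)
  if (!length(recStarts)) stop("no GenBank LOCUS lines found in ", path)
  recEnds <- grep("^//", lines)
  out <- vector("list", length(recStarts))
  for (i in seq_along(recStarts)) {
    e <- recEnds[recEnds >= recStarts[i]]
    if (!length(e)) stop("record starting at line ", recStarts[i],
                         " lacks a terminating //")
    out[[i]] <- parseOneRecord(lines[recStarts[i]:e[1]])
  }
  out
}

#' Write a Mitogenome as a GenBank flat file record
#'
#' Emits a standard LOCUS/FEATURES/ORIGIN record. Used by the synthetic-data
#' generator and for round-trip testing; appends when \code{append = TRUE}
#' so multiple records can share one file.
#'
#' @param genome a \code{\linkS4class{Mitogenome}}.
#' @param path output file path.
#' @param append append to an existing file.
#' @return \code{path}, invisibly.
#' @export
writeGenBank <- function(genome, path, append = FALSE) {
  L <- nchar(genome@sequence)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %-16s %d bp    DNA     %s INV 01-JAN-2024",
            genome@id, L, if (genome@isCircular) "circular" else "linear"))
  w("DEFINITION  mitochondrion, complete genome (synthetic).")
  w(sprintf("ACCESSION   %s", genome@id))
  w("FEATURES             Location/Qualifiers")
  w(sprintf("     source          1..%d", L))
  f <- genome@features
  for (i in seq_len(nrow(f))) {
    loc <- if (f$wraps_origin[i]) {
      sprintf("join(%d..%d,1..%d)", f$start[i] + 1L, L, f$end[i])
    } else {
      sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    }
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    w(sprintf("     %-15s %s", f$type[i], loc))
    if (nzchar(f$raw_name[i]))
      w(sprintf("                     /gene=\"%s\"", f$raw_name[i]))
    if (f$type[i] == "CDS")
      w(sprintf("                     /codon_start=%d", f$frame_offset[i] + 1L))
  }
  w("ORIGIN")
  s <- tolower(genome@sequence)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, L))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    w(sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  w("//")
  invisible(path)
}
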