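# Life-trait / taxonomy table I/O.

TAXON_RANKS <- c("class", "subclass", "order", "suborder", "infraorder",
                 "superfamily", "family", "genus")
TRAIT_NAMES <- c("feeding_habit", "habitat", "reproduction")

#' Read a species life-trait and taxonomy table
#'
#' Expects a tab-separated file with one row per species and columns
#' \code{species_id}, the eight taxonomy ranks (class ... genus) and the
#' three life traits (feeding_habit, habitat, reproduction). Categories are
#' returned verbatim; empty cells and the string \code{"NA"} become missing
#' (\code{NA}), never an empty-string category.
#'
#' @param path path to the TSV file.
#' @return data.frame keyed by \code{species_id}, one row per species.
#' @export
readTraitTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), colClasses = "character")
  required <- c("species_id", TAXON_RANKS, TRAIT_NAMES)
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("trait table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(tab$species_id))
    stop("duplicated species_id in trait table: ",
         paste(unique(tab$species_id[duplicated(tab$species_id)]),
               collapse = ", "))
  rownames(tab) <- tab$species_id
  tab
}

#' Attach taxonomy and trait labels to parsed genomes
#'
#' @param genomes list of \code{\linkS4class{Mitogenome}} objects.
#' @param traitTable data.frame from \code{\link{readTraitTable}}.
#' @return the genome list with \code{taxonomy} and \code{traits} slots
#'   filled where the species is present in the table.
#' @export
annotateGenomes <- function(genomes, traitTable) {
  lapply(genomes, function(g) {
    if (g@id %in% rownames(traitTable)) {
      row <- traitTable[g@id, ]
      g@taxonomy <- stats::setNames(
        vapply(TAXON_RANKS, function(r) as.character(row[[r]]), character(1)),
        TAXON_RANKS)
      g@traits <- stats::setNames(
        vapply(TRAIT_NAMES, function(r) as.character(row[[r]]), character(1)),
        TRAIT_NAMES)
    }
    g
  })
}
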