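#' Genetic code tables for mitochondrial coding-sequence analysis
#'
#' A \code{GeneticCode} bundles the codon -> amino-acid map of an NCBI
#' translation table together with its stop-codon set and sense-codon list.
#' The package default is translation table 5 (invertebrate mitochondrial),
#' under which AGA/AGG encode serine, ATA methionine, TGA tryptophan, and the
#' only stop codons are TAA and TAG.
#'
#' @slot id NCBI translation table identifier (e.g. \code{"5"}).
#' @slot codonMap named character vector of length 64; names are codons,
#'   values single-letter amino acids with \code{"*"} for stop.
#' @slot stops character vector of stop codons.
#' @slot senseCodons character vector of the non-stop codons.
#' @export
setClass("GeneticCode",
  representation(
    id = "character",
    codonMap = "character",
    stops = "character",
    senseCodons = "character"
  )
)

setValidity("GeneticCode", function(object) {
  msg <- character()
  if (length(object@codonMap) != 64L)
    msg <- c(msg, "codonMap must map all 64 codons")
  if (!setequal(names(object@codonMap)[object@codonMap == "*"], object@stops))
    msg <- c(msg, "stops must equal the '*' entries of codonMap")
  if (!setequal(object@senseCodons,
                names(object@codonMap)[object@codonMap != "*"]))
    msg <- c(msg, "senseCodons must be the non-stop codons")
  if (length(msg)) msg else TRUE
})

#' Construct a genetic code by NCBI translation-table number
#'
#' @param id translation table identifier accepted by
#'   \code{\link[Biostrings]{getGeneticCode}}; default \code{"5"}
#'   (invertebrate mitochondrial).
#' @return a \code{\linkS4class{GeneticCode}} object.
#' @examples
#' code <- geneticCode("5")
#' translateCodons(c("ATA", "TGA", "AGA"), code)  # "M" "W" "S"
#' @export
geneticCode <- function(id = "5") {
  map <- Biostrings::getGeneticCode(as.character(id))
  # Biostrings names codons with T already for DNA tables
  names(map) <- chartr("U", "T", names(map))
  stops <- names(map)[map == "*"]
  new("GeneticCode",
      id = as.character(id),
      codonMap = map,
      stops = stops,
      senseCodons = names(map)[map != "*"])
}

#' Translate codons under a genetic code
#'
#' @param codons character vector of 3-letter codons (A/C/G/T only).
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @return character vector of single-letter amino acids (\code{"*"} = stop);
#'   codons containing ambiguity characters translate to \code{NA}.
#' @export
translateCodons <- function(codons, code = geneticCode()) {
  unname(code@codonMap[codons])
}

#' @describeIn translateCodons logical: is each codon a stop codon?
#' @export
isStopCodon <- function(codons, code = geneticCode()) {
  codons %in% code@stops
}

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode (NCBI table ", object@id, ")\n", sep = "")
  cat("  sense codons: ", length(object@senseCodons),
      "; stops: ", paste(object@stops, collapse = ", "), "\n", sep = "")
})
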