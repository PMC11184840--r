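# End-to-end orchestration: ingest -> composition -> partition -> rates ->
# saturation -> traits, from a single validated config. Stage failures for
# single species/genes degrade to recorded missing values; a run manifest
# records seed, thresholds, versions and input digests so identical configs
# give byte-identical outputs.

#' Validate and normalize a pipeline run configuration
#'
#' @param genomes path to a GenBank flat file (or directory of \code{.gb}
#'   files).
#' @param alignments directory of per-gene \code{GENE.fasta} alignments.
#' @param traitTable path to the trait/taxonomy TSV.
#' @param outDir output directory.
#' @param seed integer seed (mandatory when any stochastic stage enabled).
#' @param tree optional Newick file fixing output row order.
#' @param outgroupIds outgroup taxon ids (default: the 5-taxon synthetic
#'   panel ids).
#' @param stages character vector of stages to run, in pipeline order.
#' @param minCodons,nReps,verdictBands,minGroupSize,minSites thresholds
#'   passed to the respective stages.
#' @return validated config list of class \code{"RunConfig"}.
#' @export
runConfig <- function(genomes, alignments, traitTable, outDir, seed,
                      tree = NULL,
                      outgroupIds = DEFAULT_OUTGROUPS,
                      stages = c("ingest", "composition", "partition",
                                 "rates", "saturation", "traits"),
                      minCodons = 30L, nReps = 500L,
                      verdictBands = c(-6, -2), minGroupSize = 2L,
                      minSites = 20L) {
  stochastic <- "saturation" %in% stages
  if (stochastic && missing(seed))
    stop("a seed is required when the saturation stage is enabled")
  if (missing(seed)) seed <- 1L
  for (p in c(genomes, alignments, traitTable, tree)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(genomes = genomes, alignments = alignments,
                 traitTable = traitTable, tree = tree, outDir = outDir,
                 outgroupIds = outgroupIds, stages = stages,
                 minCodons = as.integer(minCodons),
                 nReps = as.integer(nReps), verdictBands = verdictBands,
                 minGroupSize = as.integer(minGroupSize),
                 minSites = as.integer(minSites),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the comparative mitogenomics pipeline
#'
#' Executes the enabled stages in order and writes each stage's TSV outputs
#' plus a JSON run manifest under \code{outDir}. Per-species or per-gene
#' failures degrade to recorded missing values rather than aborting the
#' run. Reruns with the same config and inputs are byte-identical.
#'
#' @param config a \code{\link{runConfig}}.
#' @return invisible list of stage outputs (paths and data.frames).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- list(); issues <- character(0)
  code <- geneticCode()
  stage <- function(s) s %in% config$stages

  genomes <- NULL; traits <- NULL; cdsBySpecies <- NULL
  if (stage("ingest")) {
    gbFiles <- if (dir.exists(config$genomes)) {
      list.files(config$genomes, pattern = "\\.gb$", full.names = TRUE)
    } else config$genomes
    genomes <- unlist(lapply(sort(gbFiles), readGenBank), recursive = FALSE)
    traits <- readTraitTable(config$traitTable)
    genomes <- annotateGenomes(genomes, traits)
    comp <- do.call(rbind, lapply(genomes, completenessReport))
    utils::write.table(comp, file.path(config$outDir, "completeness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$completeness <- comp
  }

  if (stage("composition")) {
    if (is.null(genomes)) stop("composition stage requires ingest")
    records <- list()
    for (g in genomes) {
      rec <- tryCatch({
        og <- orientToCox1(g)
        cdss <- extractPcgs(og, code)
        genomeSummary(og, cdss)
      }, error = function(e) {
        issues <<- c(issues, paste0("composition:", g@id, ": ",
                                    conditionMessage(e)))
        NULL
      })
      if (!is.null(rec)) records[[g@id]] <- rec
    }
    tables <- compositionTable(records)
    writeCompositionTables(tables, config$outDir, config$tree)
    grouping <- stats::setNames(traits$suborder, traits$species_id)
    cs <- cladeSummary(tables$summary, grouping)
    utils::write.table(cs, file.path(config$outDir, "clade_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$composition <- tables
    out$cladeSummary <- cs
  }

  blocks <- NULL
  if (stage("partition")) {
    fastas <- sort(list.files(config$alignments, pattern = "\\.fasta$",
                              full.names = TRUE))
    blocks <- lapply(fastas, readAlignment)
    names(blocks) <- vapply(blocks, function(b) b@gene, character(1))
    concat <- concatenateBlocks(blocks)
    writeConcatenated(concat, config$outDir)
    frames <- do.call(rbind, lapply(blocks, function(b) {
      fr <- checkReadingFrame(b, code); fr$gene <- b@gene; fr
    }))
    utils::write.table(frames,
                       file.path(config$outDir, "reading_frames.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$concat <- concat
    out$frames <- frames
  }

  rates <- NULL
  if (stage("rates")) {
    if (is.null(blocks)) stop("rates stage requires partition")
    rates <- ratesTable(blocks, config$outgroupIds, code, config$minCodons)
    writeRatesTable(rates, file.path(config$outDir, "rates.tsv"))
    out$rates <- rates
  }

  if (stage("saturation")) {
    if (is.null(blocks)) stop("saturation stage requires partition")
    satRows <- list()
    for (b in blocks) {
      ingroup <- setdiff(names(b@seqs), config$outgroupIds)
      for (pos in c("1", "2", "3", "all")) {
        row <- tryCatch(
          saturationTest(b, pos, ingroup, config$nReps,
                         seed = deriveSeed(config$seed,
                                           match(b@gene, names(blocks)) * 10L
                                           + match(pos, c("1", "2", "3",
                                                          "all"))),
                         cladeLabel = "all",
                         verdictBands = config$verdictBands,
                         minSites = config$minSites),
          error = function(e) {
            issues <<- c(issues, paste0("saturation:", b@gene, ":pos", pos,
                                        ": ", conditionMessage(e)))
            NULL
          })
        if (!is.null(row)) satRows[[length(satRows) + 1L]] <- row
      }
    }
    sat <- do.call(rbind, satRows)
    utils::write.table(sat, file.path(config$outDir, "saturation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$saturation <- sat
  }

  if (stage("traits")) {
    if (is.null(traits)) stop("traits stage requires ingest")
    merged <- traits
    metrics <- character(0)
    if (!is.null(out$composition)) {
      merged <- merge(merged, out$composition$summary, by = "species_id",
                      all.x = TRUE)
      metrics <- c("genome_length", "pcg_total_length", "pcg_proportion",
                   "genome_pct_gc", "pcg_pct_gc", "pcg_gc_skew",
                   "pcg_at_skew")
    }
    if (!is.null(rates)) {
      perSp <- stats::aggregate(rates[, c("dN_mean", "dS_mean")],
                                by = list(species_id = rates$species_id),
                                FUN = function(v) if (all(is.na(v)))
                                  NA_real_ else mean(v, na.rm = TRUE))
      merged <- merge(merged, perSp, by = "species_id", all.x = TRUE)
      metrics <- c(metrics, "dN_mean", "dS_mean")
    }
    if (length(metrics)) {
      battery <- traitBattery(merged, metrics,
                              groupings = c("feeding_habit", "habitat",
                                            "reproduction", "suborder",
                                            "family"),
                              block = "suborder",
                              minGroupSize = config$minGroupSize)
      utils::write.table(battery,
                         file.path(config$outDir, "trait_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      dunnRows <- list()
      for (m in metrics) {
        for (g in c("feeding_habit", "habitat", "reproduction")) {
          d <- tryCatch(dunnPosthoc(merged[[m]], merged[[g]],
                                    config$minGroupSize),
                        error = function(e) NULL)
          if (!is.null(d)) {
            d$metric <- m; d$grouping <- g
            dunnRows[[length(dunnRows) + 1L]] <- d
          }
        }
      }
      if (length(dunnRows)) {
        dunn <- do.call(rbind, dunnRows)
        utils::write.table(dunn, file.path(config$outDir, "dunn_tests.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out$dunn <- dunn
      }
      out$traitTests <- battery
    }
  }

  manifest <- list(
    package = "mitocompare",
    version = as.character(utils::packageVersion("mitocompare")),
    stages = config$stages,
    seed = config$seed,
    thresholds = list(min_codons = config$minCodons,
                      n_reps = config$nReps,
                      verdict_bands = config$verdictBands,
                      min_group_size = config$minGroupSize,
                      min_sites = config$minSites),
    estimator_notes = c(
      "rates: Nei-Gojobori-type counting estimator with Jukes-Cantor correction (not ML)",
      "saturation: entropy index vs Monte-Carlo full-saturation null (not DAMBE critical values)",
      "genome skews computed post COX1 orientation on the stored strand",
      "dN:dS reported as ratio of outgroup-averaged rates"),
    input_md5 = as.list(tools::md5sum(stats::na.omit(c(
      if (dir.exists(config$genomes)) NULL else config$genomes,
      config$traitTable, config$tree)))),
    issues = issues)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$issues <- issues
  invisible(out)
}
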