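#' Default pipeline configuration
#'
#' One namespace for every tunable of the discovery pipeline, so the
#' thresholds behind each analysis decision are auditable in one
#' place. Any subset can be overridden via `config` in
#' [runPipeline()] or a YAML file.
#'
#' @return nested named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    scan = list(tir_mm = 2L, tsd_mm = 2L, max_score = 2L,
                min_len = 50L, max_len = 30000L, rescue = FALSE),
    classify = classifyThresholds(),
    annotate = list(repeat_threshold = 2.0, k = 20L, flank = 200L),
    cluster = list(k = 8L, n_clusters = 3L, class = "Ds-l4",
                   exclude_longer_than = 5000L),
    seed = 1L)
}

#' Run the discovery pipeline end to end
#'
#' scan -> classify -> annotate -> report, writing a TSV catalog, a
#' GFF3 catalog and census tables into `outDir`. Deterministic for a
#' fixed configuration: scanning and classification contain no
#' randomness.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param acRef [AcReference-class] (or `NULL` to use the seeded
#'   synthetic reference, for self-contained runs).
#' @param outDir output directory.
#' @param geneModels optional `GRanges` or GFF3 path of gene models.
#' @param ds1Consensus optional Ds1 family consensus (character,
#'   `DNAString`, or FASTA path).
#' @param config optional list overriding [defaultConfig()] entries, or
#'   a YAML file path.
#' @return invisible list with `catalog` (classified + annotated
#'   `GRanges`), `census` (chromosome x class matrix), `config`.
#' @export
runPipeline <- function(genome, acRef = NULL, outDir = tempfile("acds_"),
                        geneModels = NULL, ds1Consensus = NULL,
                        config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(defaultConfig(), config)
  if (is.character(genome)) genome <- readGenome(genome)
  if (is.null(acRef)) acRef <- makeAcReference(cfg$seed)
  if (is.character(geneModels)) geneModels <- readGeneModels(geneModels)
  if (is.character(ds1Consensus) && file.exists(ds1Consensus))
    ds1Consensus <- as.character(readGenome(ds1Consensus)[[1]])
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  message("stage scan")
  catalog <- scanElements(genome, tirMaxMismatch = cfg$scan$tir_mm,
                          minLen = cfg$scan$min_len,
                          maxLen = cfg$scan$max_len,
                          tsdMaxMismatch = cfg$scan$tsd_mm,
                          maxScore = cfg$scan$max_score)
  if (isTRUE(cfg$scan$rescue)) {
    rescued <- rescueNoTSD(genome, catalog, minLen = cfg$scan$min_len,
                           maxLen = cfg$scan$max_len,
                           maxScore = cfg$scan$max_score)
    writeCatalog(rescued, file.path(outDir, "rescued.tsv"))
  }
  message("stage classify")
  catalog <- suppressWarnings(
    classifyCatalog(catalog, genome, acRef, ds1Consensus = ds1Consensus,
                    thresholds = cfg$classify))
  message("stage annotate")
  catalog <- annotateCatalog(catalog, genome, geneModels = geneModels,
                             repeatThreshold = cfg$annotate$repeat_threshold,
                             k = cfg$annotate$k, flank = cfg$annotate$flank)
  message("stage report")
  census <- summarizeCounts(catalog, rows = "chromosome", cols = "class")
  writeCatalog(catalog, file.path(outDir, "catalog.tsv"), format = "tsv")
  writeCatalog(catalog, file.path(outDir, "catalog.gff3"), format = "gff3")
  write.table(census, file.path(outDir, "census.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
  invisible(list(catalog = catalog, census = census, config = cfg))
}
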