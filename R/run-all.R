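#' @include simulate.R
NULL

#' Serialize a phylogenetic core to JSON
#'
#' Writes one record per core OTU (id, detection threshold, representative id
#' and sequence, per-sample counts, claimed member ids) plus the run context
#' (threshold grid, prevalence, sample ids and depths). The file round-trips
#' through [readPhylogeneticCore()] up to the per-level tables, which are not
#' serialized.
#'
#' @param core A [PhylogeneticCore-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCoreJSON <- function(core, path) {
  stopifnot(is(core, "PhylogeneticCore"))
  obj <- list(
    prevalence = jsonlite::unbox(core@prevalence),
    thresholdGrid = core@thresholdGrid,
    sampleIds = core@sampleIds,
    sampleDepths = as.list(core@sampleDepths),
    nSequences = jsonlite::unbox(core@nSequences),
    cores = lapply(core@cores, function(co) list(
      otuId = jsonlite::unbox(co@otuId),
      detectionThreshold = jsonlite::unbox(co@detectionThreshold),
      representativeId = jsonlite::unbox(co@representativeId),
      representativeSeq = jsonlite::unbox(as.character(co@representativeSeq)),
      perSampleCounts = as.list(co@perSampleCounts),
      maskedMemberIds = co@maskedMemberIds
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeCoreJSON
#' @param path Path of a file written by `writeCoreJSON`.
#' @return `readPhylogeneticCore`: a [PhylogeneticCore-class] with empty
#'   `levelTables`.
#' @export
readPhylogeneticCore <- function(path) {
  .stop_if(!file.exists(path), "core JSON not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cores <- lapply(obj$cores, function(co) {
    rep_seq <- Biostrings::DNAStringSet(co$representativeSeq)
    names(rep_seq) <- co$otuId
    new("CoreOTU",
        otuId = co$otuId,
        detectionThreshold = as.numeric(co$detectionThreshold),
        representativeId = co$representativeId,
        representativeSeq = rep_seq,
        maskedMemberIds = unlist(co$maskedMemberIds),
        perSampleCounts = unlist(co$perSampleCounts))
  })
  obj_samples <- unlist(obj$sampleIds)
  new("PhylogeneticCore",
      cores = cores,
      prevalence = as.numeric(obj$prevalence),
      thresholdGrid = unlist(obj$thresholdGrid),
      sampleIds = obj_samples,
      sampleDepths = unlist(obj$sampleDepths)[obj_samples],
      levelTables = list(),
      nSequences = as.integer(obj$nSequences))
}

#' Run the full dynamic-core workflow
#'
#' Composes the pipeline end to end: read (or accept) the dataset, subsample
#' to common depth, cluster along the ladder, detect the dynamic core, run
#' the per-level permutation test, summarize, and optionally attach consensus
#' taxonomy and a reference-match report. All outputs land in `outDir`:
#' `core.json`, `summary.json`, `permutation.json`, `representatives.fasta`,
#' per-level `table_<t>.tsv`, the resolved `config.yaml` and a
#' `manifest.json` with package version, seed and input checksums. All
#' randomness derives from the single `seed` via stage-keyed seeds, so a
#' rerun with the same config is byte-identical.
#'
#' @param config Either a path to a YAML file or a named list with entries:
#'   `input` (FASTA path) and optional `sampleMap`, `headerStyle`,
#'   `minLength`, `thresholds` (descending numeric), `prevalence`,
#'   `nPermutations`, `seed`, `recluster`, `taxonomy` (taxonomy TSV path),
#'   `references` (FASTA path), `outDir`.
#' @param dataset Optionally, an [AmpliconDataset-class] to use directly
#'   (skips `input`).
#' @return The output directory path, invisibly; side effect: files written.
#' @export
runAll <- function(config, dataset = NULL) {
  if (is.character(config) && length(config) == 1L) {
    .stop_if(!file.exists(config), "config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- list(
    input = config$input,
    sampleMap = config$sampleMap,
    headerStyle = if (is.null(config$headerStyle)) "qiime_underscore"
                  else config$headerStyle,
    minLength = if (is.null(config$minLength)) 75 else config$minLength,
    thresholds = if (is.null(config$thresholds)) defaultThresholds()
                 else as.numeric(config$thresholds),
    prevalence = if (is.null(config$prevalence)) 1 else config$prevalence,
    nPermutations = if (is.null(config$nPermutations)) 100
                    else config$nPermutations,
    seed = if (is.null(config$seed)) 1L else as.integer(config$seed),
    recluster = isTRUE(config$recluster),
    taxonomy = config$taxonomy,
    references = config$references,
    outDir = config$outDir
  )
  .stop_if(is.null(cfg$outDir), "config must name an outDir")
  if (is.null(dataset)) {
    .stop_if(is.null(cfg$input), "config must name an input FASTA")
    .stop_if(!file.exists(cfg$input), "input not found: ", cfg$input)
  }
  for (p in c(cfg$sampleMap, cfg$taxonomy, cfg$references))
    .stop_if(!is.null(p) && !file.exists(p), "input not found: ", p)

  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  checksums <- list()
  for (p in c(cfg$input, cfg$sampleMap, cfg$taxonomy, cfg$references))
    if (!is.null(p))
      checksums[[basename(p)]] <- jsonlite::unbox(unname(tools::md5sum(p)))

  if (is.null(dataset))
    dataset <- readFastaWithSamples(cfg$input, cfg$sampleMap,
                                    cfg$headerStyle, cfg$minLength)
  dataset <- subsampleCommonDepth(dataset,
                                  seed = deriveSeed(cfg$seed, "subsample"))
  core <- runDynamicCore(dataset, thresholds = cfg$thresholds,
                         prevalence = cfg$prevalence,
                         recluster = cfg$recluster)
  perms <- permutationTestAllLevels(core, nPermutations = cfg$nPermutations,
                                    seed = cfg$seed)
  summ <- coreSummary(core)
  summ$pValues <- vapply(perms, function(x) x@pValue, numeric(1))

  writeCoreJSON(core, file.path(cfg$outDir, "core.json"))
  jsonlite::write_json(
    list(frequency = as.list(summ$frequency),
         perLevelCounts = as.list(summ$perLevelCounts),
         coreGroups = jsonlite::unbox(formatCoreGroups(core)),
         perCore = summ$perCore,
         pValues = as.list(summ$pValues)),
    file.path(cfg$outDir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    lapply(perms, function(x) list(
      threshold = jsonlite::unbox(x@threshold),
      observed = jsonlite::unbox(x@observedCoreCount),
      pValue = jsonlite::unbox(x@pValue),
      nullCounts = x@nullCounts)),
    file.path(cfg$outDir, "permutation.json"), digits = NA, pretty = TRUE)

  reps <- Biostrings::DNAStringSet(vapply(core@cores, function(co)
    as.character(co@representativeSeq), character(1)))
  names(reps) <- vapply(core@cores, function(co)
    paste0(co@otuId, " ", co@representativeId), character(1))
  Biostrings::writeXStringSet(reps,
                              file.path(cfg$outDir, "representatives.fasta"))

  for (lv in names(core@levelTables))
    writeOTUTable(core@levelTables[[lv]],
                  file.path(cfg$outDir, sprintf("table_%s.tsv", lv)))

  if (!is.null(cfg$taxonomy)) {
    tax <- readTaxonomyFile(cfg$taxonomy)
    tt <- coreConsensusTaxonomy(core, dataset, tax)
    write.table(tt, file.path(cfg$outDir, "taxonomy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cfg$references)) {
    refs <- Biostrings::readDNAStringSet(cfg$references)
    names(refs) <- sub("\\s.*$", "", names(refs))
    rr <- refmatchReport(core, dataset, refs)
    write.table(rr, file.path(cfg$outDir, "refmatch.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(cfg$outDir, "config.yaml"))
  jsonlite::write_json(
    list(package = jsonlite::unbox("phylocore"),
         version = jsonlite::unbox(as.character(packageVersion("phylocore"))),
         seed = jsonlite::unbox(cfg$seed),
         inputChecksums = checksums,
         nSequences = jsonlite::unbox(length(dataset)),
         nSamples = jsonlite::unbox(length(sampleNames(dataset)))),
    file.path(cfg$outDir, "manifest.json"), digits = NA, pretty = TRUE)

  invisible(cfg$outDir)
}
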