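#' @include core-stats.R
NULL

#' Parse a mothur-dialect taxonomy string
#'
#' Accepts lineages of the form `Bacteria(100);Firmicutes(98);...;` with
#' per-rank bootstrap confidences in percent (or fractions in `[0, 1]`);
#' ranks without a parenthesised confidence get confidence 1.
#'
#' @param x A single taxonomy string.
#' @return A `data.frame` with columns `taxon` and `confidence` (fractions),
#'   ordered root to leaf.
#' @export
#' @examples
#' parseTaxonomyString("Bacteria(100);Firmicutes(95);Clostridia(80);")
parseTaxonomyString <- function(x) {
  stopifnot(length(x) == 1L, is.character(x))
  parts <- strsplit(sub(";+$", "", x), ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L)
    return(data.frame(taxon = character(0), confidence = numeric(0)))
  has_conf <- grepl("\\(([0-9.]+)\\)$", parts)
  conf <- rep(1, length(parts))
  conf[has_conf] <- as.numeric(sub("^.*\\(([0-9.]+)\\)$", "\\1",
                                   parts[has_conf]))
  conf[conf > 1] <- conf[conf > 1] / 100
  taxon <- sub("\\(([0-9.]+)\\)$", "", parts)
  data.frame(taxon = taxon, confidence = conf)
}

#' Read per-sequence taxonomy assignments
#'
#' Reads a mothur-style `.taxonomy` file: two tab-separated columns,
#' `seq_id TAB lineage`, where the lineage uses the dialect of
#' [parseTaxonomyString()].
#'
#' @param path Path to the taxonomy TSV.
#' @return Named list (seq id -> lineage `data.frame`).
#' @export
readTaxonomyFile <- function(path) {
  .stop_if(!file.exists(path), "taxonomy file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "", comment.char = "")
  .stop_if(ncol(tab) < 2L, "taxonomy file must have two tab-separated columns")
  .stop_if(anyDuplicated(tab[[1L]]) > 0L,
           "duplicated sequence id in taxonomy file: ",
           tab[[1L]][anyDuplicated(tab[[1L]])])
  out <- lapply(tab[[2L]], parseTaxonomyString)
  names(out) <- tab[[1L]]
  out
}

#' Re-cluster a core OTU's members at species level
#'
#' Clusters the core's masked member sequences de novo at the given threshold
#' (default 0.97) and returns the representative sequences, which are the
#' units taken forward for taxonomy assignment and reference matching. Exact
#' duplicates are collapsed before clustering (weights accumulate), so the
#' representatives are always a subset of the core's masked members.
#'
#' @param coreOtu A [CoreOTU-class].
#' @param dataset The [AmpliconDataset-class] the core was detected in.
#' @param threshold Identity threshold (default 0.97).
#' @return A [Biostrings::DNAStringSet] of representatives named by their
#'   sequence ids.
#' @export
subclusterCore <- function(coreOtu, dataset, threshold = 0.97) {
  stopifnot(is(coreOtu, "CoreOTU"), is(dataset, "AmpliconDataset"))
  idx <- match(coreOtu@maskedMemberIds, seqIds(dataset))
  .stop_if(anyNA(idx), "core members missing from the dataset")
  ids <- seqIds(dataset)[idx]
  seqs <- as.character(dataset@sequences)[idx]
  first_idx <- which(!duplicated(seqs))
  uniq_seqs <- seqs[first_idx]
  uniq_ids <- ids[first_idx]
  wts <- as.numeric(table(factor(uniq_ids[match(seqs, uniq_seqs)],
                                 levels = uniq_ids)))
  res <- greedyCluster(uniq_ids, uniq_seqs, weights = wts,
                       threshold = threshold)
  reps <- res@representativeSeqs
  names(reps) <- unname(res@representativeIds)
  reps
}

#' Consensus taxonomy over a set of lineage assignments
#'
#' Each input lineage is first truncated at the first rank whose confidence
#' falls below `minConfidence` (the per-sequence classifier cutoff, default
#' 0.80). Walking root to leaf, the consensus keeps the taxon whose full
#' prefix is shared by at least a `cutoff` fraction of all inputs at each
#' rank and stops at the first rank where no taxon reaches the cutoff. The
#' reported support is the shared fraction at the deepest kept rank. Ties at
#' a rank (possible only when `cutoff <= 0.5`) are broken toward the
#' lexicographically smallest taxon.
#'
#' @param assignments Non-empty list of lineage `data.frame`s (see
#'   [parseTaxonomyString()]).
#' @param cutoff Consensus fraction in `(0, 1]` (default 0.51, the usual
#'   majority-consensus default).
#' @param minConfidence Per-sequence confidence floor (default 0.80).
#' @return A list: `lineage` (character vector of kept taxa, possibly
#'   empty = unclassified), `support` (fraction at the deepest kept rank, NA
#'   if the lineage is empty), `nInputs`.
#' @export
#' @examples
#' lins <- lapply(c("Firmicutes(100);Clostridia(100);Lachnospiraceae(100);",
#'                  "Firmicutes(100);Clostridia(100);Lachnospiraceae(90);",
#'                  "Firmicutes(100);Clostridia(100);Lachnospiraceae(85);",
#'                  "Firmicutes(100);Clostridia(100);Ruminococcaceae(99);"),
#'                parseTaxonomyString)
#' consensusTaxonomy(lins)  # stops at family Lachnospiraceae, support 0.75
consensusTaxonomy <- function(assignments, cutoff = 0.51,
                              minConfidence = 0.80) {
  .stop_if(length(assignments) == 0L,
           "consensus requires at least one assignment")
  stopifnot(cutoff > 0, cutoff <= 1)
  truncated <- lapply(assignments, function(lin) {
    if (nrow(lin) == 0L) return(character(0))
    low <- which(lin$confidence < minConfidence)
    keep <- if (length(low)) seq_len(low[1L] - 1L) else seq_len(nrow(lin))
    lin$taxon[keep]
  })
  n <- length(truncated)
  consensus <- character(0)
  support <- NA_real_
  depth <- 1L
  repeat {
    candidates <- vapply(truncated, function(tx) {
      if (length(tx) < depth) return(NA_character_)
      if (depth > 1L &&
          !identical(tx[seq_len(depth - 1L)], consensus))
        return(NA_character_)
      tx[depth]
    }, character(1))
    candidates <- candidates[!is.na(candidates)]
    if (length(candidates) == 0L) break
    votes <- sort(table(candidates), decreasing = TRUE)
    # lexicographically smallest among tied top taxa
    top <- names(votes)[votes == votes[1L]]
    winner <- sort(top, method = "radix")[1L]
    frac <- as.integer(votes[[winner]]) / n
    if (frac < cutoff) break
    consensus <- c(consensus, winner)
    support <- frac
    depth <- depth + 1L
  }
  list(lineage = consensus, support = support, nInputs = n)
}

#' Consensus taxonomy for every core OTU
#'
#' For each core OTU, re-clusters its members at `threshold` (default 0.97),
#' looks up the representatives' per-sequence assignments and reduces them to
#' a consensus lineage via [consensusTaxonomy()].
#'
#' @param core A [PhylogeneticCore-class].
#' @param dataset The analyzed [AmpliconDataset-class].
#' @param taxonomy Named list of lineages as from [readTaxonomyFile()]; must
#'   cover the representatives.
#' @param cutoff,minConfidence Passed to [consensusTaxonomy()].
#' @param threshold Sub-clustering threshold (default 0.97).
#' @return A `data.frame`: `otuId`, `threshold`, `lineage` (semicolon
#'   joined), `support`, `nInputs`.
#' @export
coreConsensusTaxonomy <- function(core, dataset, taxonomy, cutoff = 0.51,
                                  minConfidence = 0.80, threshold = 0.97) {
  stopifnot(is(core, "PhylogeneticCore"))
  rows <- lapply(core@cores, function(co) {
    reps <- subclusterCore(co, dataset, threshold)
    missing <- setdiff(names(reps), names(taxonomy))
    .stop_if(length(missing) > 0L,
             "representative(s) missing from taxonomy: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    cons <- consensusTaxonomy(taxonomy[names(reps)], cutoff, minConfidence)
    data.frame(otuId = co@otuId, threshold = co@detectionThreshold,
               lineage = paste(cons$lineage, collapse = ";"),
               support = cons$support, nInputs = cons$nInputs,
               row.names = NULL)
  })
  if (length(rows) == 0L)
    return(data.frame(otuId = character(0), threshold = numeric(0),
                      lineage = character(0), support = numeric(0),
                      nInputs = integer(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
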