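#' @include taxonomy.R
NULL

#' Best identity of a query against a reference collection
#'
#' Exhaustive [pairwiseIdentity()] of the query against every reference; the
#' maximum is returned, with ties broken toward the lexicographically
#' smallest reference id.
#'
#' @param query A DNA string.
#' @param references A named [Biostrings::DNAStringSet] (or named character
#'   vector) of reference 16S sequences.
#' @return A list: `refId`, `identity`.
#' @export
bestIdentity <- function(query, references) {
  .stop_if(length(references) == 0L, "empty reference set")
  refs <- setNames(as.character(references), names(references))
  .stop_if(is.null(names(refs)) || any(!nzchar(names(refs))),
           "references must be named")
  sims <- .identityMany(query, refs)
  best <- max(sims)
  tied <- names(refs)[sims == best]
  list(refId = sort(tied, method = "radix")[1L], identity = best)
}

#' Reference-genome coverage report for a phylogenetic core
#'
#' Quantifies how well a reference 16S collection covers the detected core:
#' each core OTU is re-clustered at 0.97 ([subclusterCore()]), each
#' within-core representative is matched against the references
#' ([bestIdentity()]), and the best identities are aggregated per core OTU as
#' mean and standard deviation (sd over a single representative is 0).
#'
#' With `requireSpanning = TRUE` (default), references shorter than the query
#' are excluded for that query, so a fragment cannot score a spuriously
#' perfect contained match; set to `FALSE` to allow any overlap.
#'
#' @param core A [PhylogeneticCore-class].
#' @param dataset The analyzed [AmpliconDataset-class].
#' @param references Named [Biostrings::DNAStringSet] of reference sequences.
#' @param requireSpanning Logical (default `TRUE`).
#' @param threshold Sub-clustering threshold (default 0.97).
#' @return A `data.frame`: `otuId`, `threshold`, `meanBestIdentity`,
#'   `sdBestIdentity`, `nReps`, `bestRefIds` (comma joined).
#' @export
refmatchReport <- function(core, dataset, references,
                           requireSpanning = TRUE, threshold = 0.97) {
  stopifnot(is(core, "PhylogeneticCore"), is(dataset, "AmpliconDataset"))
  .stop_if(length(references) == 0L, "empty reference set")
  refs <- setNames(as.character(references), names(references))
  rows <- lapply(core@cores, function(co) {
    reps <- subclusterCore(co, dataset, threshold)
    hits <- lapply(as.character(reps), function(q) {
      use <- if (requireSpanning) refs[nchar(refs) >= nchar(q)] else refs
      .stop_if(length(use) == 0L,
               "no reference spans the query region (", nchar(q), " nt)")
      bestIdentity(q, use)
    })
    ident <- vapply(hits, `[[`, numeric(1), "identity")
    data.frame(otuId = co@otuId, threshold = co@detectionThreshold,
               meanBestIdentity = mean(ident),
               sdBestIdentity = if (length(ident) > 1) sd(ident) else 0,
               nReps = length(ident),
               bestRefIds = paste(unique(vapply(hits, `[[`, character(1),
                                                "refId")),
                                  collapse = ","),
               row.names = NULL)
  })
  if (length(rows) == 0L)
    return(data.frame(otuId = character(0), threshold = numeric(0),
                      meanBestIdentity = numeric(0),
                      sdBestIdentity = numeric(0), nReps = integer(0),
                      bestRefIds = character(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
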