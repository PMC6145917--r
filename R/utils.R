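#' @include AllGenerics.R
NULL

## Run expr with a temporarily-seeded RNG, restoring global RNG state after.
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Derive a stage-specific seed from a master seed
#'
#' All randomness in a pipeline run flows from one master seed; each stage
#' (subsampling, per-level permutations, simulation, ...) draws its own seed
#' through a deterministic keyed hash of the stage name, so stages stay
#' reproducible independently of one another.
#'
#' @param seed Integer master seed.
#' @param stage Character stage key, e.g. `"subsample"` or `"permute_0.97"`.
#' @return An integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' deriveSeed(1, "subsample")
deriveSeed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  u <- utf8ToInt(stage)
  h <- sum(u * (seq_along(u) %% 61L + 1L)) %% 1048573
  as.integer((abs(as.numeric(seed)) * 1009 + h * 2654435) %% 2147483587)
}

## Per-element threshold labels ("0.9", "0.97"), independent of the other
## grid values (vector format() would pad to a common width).
.thrLabels <- function(x) vapply(x, function(t) format(t), character(1))

## Deterministic C-locale ordering helpers (radix method is locale-independent).
.orderBy <- function(...) order(..., method = "radix")

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

## Construct an AmpliconDataset from parallel vectors.
.newDataset <- function(ids, seqs, samples_of) {
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  new("AmpliconDataset",
      sequences = dss,
      sampleIds = as.character(samples_of),
      samples = unique(as.character(samples_of)))
}

## Sparse samples x OTUs table constructor; tolerates dense input and the
## symmetric/triangular classes Matrix() may auto-detect.
.newOTUTable <- function(counts, threshold) {
  m <- Matrix::Matrix(counts, sparse = TRUE)
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  new("OTUTable", counts = m, threshold = threshold)
}
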