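#' @include utils.R
NULL

#' Read demultiplexed amplicon sequences with sample attribution
#'
#' Reads a FASTA file of demultiplexed reads and attributes every sequence to
#' a sample, either from QIIME-style headers (`sampleID_N`, split on the first
#' underscore) or from a separate two-column tab-separated map
#' (`seq_id TAB sample_id`, no header). Lowercase residues are uppercased and
#' `N`-containing sequences are retained.
#'
#' @param fastaPath Path to a FASTA file (wrapped or unwrapped).
#' @param sampleMap Optional path to the two-column map file; required when
#'   `headerStyle = "map_file"`.
#' @param headerStyle `"qiime_underscore"` (default) or `"map_file"`.
#' @param minLength Sequences shorter than this many nt are rejected at read
#'   time (default 75; guards the alignment kernel against degenerate reads).
#' @return An [AmpliconDataset-class].
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">S1_1", "ACGTACGTACGTACGTACGT", ">S2_1",
#'              "ACGTACGTACGTACGTACGA"), fa)
#' readFastaWithSamples(fa, minLength = 10)
readFastaWithSamples <- function(fastaPath, sampleMap = NULL,
                                 headerStyle = c("qiime_underscore",
                                                 "map_file"),
                                 minLength = 75) {
  headerStyle <- match.arg(headerStyle)
  .stop_if(!file.exists(fastaPath), "FASTA file not found: ", fastaPath)
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  .stop_if(length(seqs) == 0L, "empty FASTA file: ", fastaPath)
  # header may carry a description after whitespace; the id is the first token
  ids <- sub("\\s.*$", "", names(seqs))
  .stop_if(anyDuplicated(ids) > 0L,
           "duplicated sequence id in FASTA: ",
           ids[anyDuplicated(ids)])
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- ids

  short <- Biostrings::width(seqs) < minLength
  .stop_if(all(short), "all sequences shorter than minLength = ", minLength)
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than ", minLength,
            " nt rejected at read time", call. = FALSE)
    seqs <- seqs[!short]
    ids <- ids[!short]
  }

  if (headerStyle == "map_file") {
    .stop_if(is.null(sampleMap), "headerStyle 'map_file' requires sampleMap")
    map <- read.table(sampleMap, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = "")
    .stop_if(ncol(map) < 2L, "sample map must have two tab-separated columns")
    lookup <- setNames(map[[2L]], map[[1L]])
    missing <- setdiff(ids, names(lookup))
    .stop_if(length(missing) > 0L,
             "sequence id(s) missing from sample map: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    samples_of <- unname(lookup[ids])
  } else {
    .stop_if(!all(grepl("_", ids)),
             "qiime_underscore headers require a 'sampleID_N' id; offending: ",
             ids[which(!grepl("_", ids))[1L]])
    samples_of <- sub("_.*$", "", ids)
  }

  .newDataset(ids, as.character(seqs), samples_of)
}

#' Subsample every sample to the common (minimum) depth
#'
#' Classic rarefaction: each sample is subsampled without replacement to the
#' dataset's minimum per-sample depth, so all samples end at equal depth.
#' Drawn records are preserved verbatim; input order among kept records is
#' preserved. Deterministic given `seed`.
#'
#' @param dataset An [AmpliconDataset-class].
#' @param seed Integer seed (mandatory).
#' @return An [AmpliconDataset-class] at common depth.
#' @export
subsampleCommonDepth <- function(dataset, seed) {
  stopifnot(is(dataset, "AmpliconDataset"))
  .stop_if(missing(seed), "subsampleCommonDepth requires a seed")
  depths <- sampleDepths(dataset)
  .stop_if(any(depths == 0), "every sample must have at least one sequence")
  d <- min(depths)
  keep <- .withSeed(seed, {
    idx <- unlist(lapply(dataset@samples, function(s) {
      pos <- which(dataset@sampleIds == s)
      if (length(pos) == d) pos else sort(sample(pos, d))
    }), use.names = FALSE)
    sort(idx)
  })
  .newDataset(seqIds(dataset)[keep],
              as.character(dataset@sequences[keep]),
              dataset@sampleIds[keep])
}

#' Write / read an OTU table
#'
#' The TSV dialect stores OTUs as rows (first column `#OTU_ID`, one column per
#' sample) preceded by a `# threshold=<t>` comment line. The `biom_json`
#' dialect writes a BIOM v1 (JSON) file via the biomformat package, carrying
#' the threshold in the table id. `readOTUTable` is the inverse:
#' `readOTUTable(writeOTUTable(x))` reproduces labels, counts and threshold.
#'
#' @param table An [OTUTable-class].
#' @param path Output (input) file path.
#' @param format `"tsv"` (default) or `"biom_json"`.
#' @return `writeOTUTable` returns `path` invisibly; `readOTUTable` returns an
#'   [OTUTable-class].
#' @export
writeOTUTable <- function(table, path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  stopifnot(is(table, "OTUTable"))
  m <- as.matrix(otuCounts(table))
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# threshold=%s",
                       format(table@threshold, digits = 15)), con)
    writeLines(paste(c("#OTU_ID", rownames(m)), collapse = "\t"), con)
    if (ncol(m) > 0)
      for (j in seq_len(ncol(m)))
        writeLines(paste(c(colnames(m)[j],
                           format(m[, j], scientific = FALSE, trim = TRUE)),
                         collapse = "\t"), con)
  } else {
    .stop_if(!requireNamespace("biomformat", quietly = TRUE),
             "the biomformat package is required for biom_json output")
    b <- biomformat::make_biom(t(m),
                               id = sprintf("threshold=%s",
                                            format(table@threshold,
                                                   digits = 15)))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' @rdname writeOTUTable
#' @export
readOTUTable <- function(path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  .stop_if(!file.exists(path), "OTU table file not found: ", path)
  if (format == "tsv") {
    lines <- readLines(path)
    .stop_if(length(lines) < 2L, "malformed OTU table (line 1): too short")
    thr_line <- grep("^# threshold=", lines)
    .stop_if(length(thr_line) != 1L,
             "malformed OTU table (line 1): missing '# threshold=' comment")
    threshold <- suppressWarnings(
      as.numeric(sub("^# threshold=", "", lines[thr_line])))
    .stop_if(is.na(threshold),
             "malformed OTU table (line ", thr_line, "): bad threshold")
    hdr_line <- grep("^#OTU_ID\t|^#OTU_ID$", lines)
    .stop_if(length(hdr_line) != 1L,
             "malformed OTU table (line 2): missing '#OTU_ID' header")
    samples <- strsplit(lines[hdr_line], "\t", fixed = TRUE)[[1L]][-1L]
    body <- lines[-seq_len(hdr_line)]
    body <- body[nzchar(body)]
    if (length(body) == 0L) {
      m <- matrix(0, nrow = length(samples), ncol = 0,
                  dimnames = list(samples, character(0)))
      return(.newOTUTable(m, threshold))
    }
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) != length(samples) + 1L)
    .stop_if(length(bad) > 0L,
             "malformed OTU table (line ", hdr_line + bad[1L],
             "): wrong field count")
    otus <- vapply(parts, `[[`, character(1), 1L)
    vals <- vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[-1L]))
      v
    }, numeric(length(samples)))
    bad <- which(apply(is.na(rbind(vals)), 2L, any))
    .stop_if(length(bad) > 0L,
             "malformed OTU table (line ", hdr_line + bad[1L],
             "): non-numeric count")
    m <- matrix(rbind(vals), nrow = length(samples), ncol = length(otus),
                dimnames = list(samples, otus))
    .newOTUTable(m, threshold)
  } else {
    .stop_if(!requireNamespace("biomformat", quietly = TRUE),
             "the biomformat package is required for biom_json input")
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
    id <- tryCatch(b$id, error = function(e) NULL)
    threshold <- if (!is.null(id) && grepl("^threshold=", id))
      as.numeric(sub("^threshold=", "", id)) else NA_real_
    .stop_if(is.na(threshold),
             "BIOM table id does not carry 'threshold=<t>' metadata")
    .newOTUTable(m, threshold)
  }
}
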