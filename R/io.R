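#' Read a multi-channel recording from delimited text
#'
#' Reads a comma-separated matrix with one row per channel and one column per
#' sample. An optional first row of (non-numeric) channel labels is detected
#' and captured. Ragged rows and non-numeric cells are rejected with the
#' offending line named.
#'
#' @param path path to the CSV file.
#' @param fs sampling rate in Hz (not stored in the CSV).
#' @param format only `"csv"` is supported.
#'
#' @return a [MultiChannelRecording-class].
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, fs, format = "csv") {
  if (format != "csv") stop("unsupported format: ", format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty file: ", path)
  cells <- strsplit(lines, ",", fixed = TRUE)
  labels <- character()
  first <- suppressWarnings(as.numeric(cells[[1L]]))
  if (anyNA(first)) {
    labels <- trimws(cells[[1L]])
    cells <- cells[-1L]
    if (length(cells) < 1L) stop("no data rows in ", path)
  }
  lens <- lengths(cells)
  if (any(lens != lens[1L]))
    stop("ragged rows: line ", which(lens != lens[1L])[1L] +
      (length(labels) > 0L), " has ", lens[lens != lens[1L]][1L],
      " fields, expected ", lens[1L])
  rows <- lapply(seq_along(cells), function(i) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v))
      stop("non-numeric cell in data row ", i, ", field ",
        which(is.na(v))[1L])
    v
  })
  multiChannelRecording(do.call(rbind, rows), fs = fs,
    channelLabels = labels)
}

#' Write a multi-channel recording as delimited text
#'
#' Inverse of [readRecording()]: channels as rows, full double precision
#' (`%.17g`), channel labels as an optional header row.
#'
#' @param recording a [MultiChannelRecording-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRecording <- function(recording, path) {
  stopifnot(is(recording, "MultiChannelRecording"))
  lines <- apply(recording@data, 1L,
    function(r) paste(sprintf("%.17g", r), collapse = ","))
  if (length(recording@channelLabels))
    lines <- c(paste(recording@channelLabels, collapse = ","), lines)
  writeLines(lines, path)
  invisible(path)
}

.writeMatrixCsv <- function(m, path) {
  writeLines(apply(m, 1L,
    function(r) paste(sprintf("%.17g", r), collapse = ",")), path)
  invisible(path)
}

.readMatrixCsv <- function(path) {
  do.call(rbind, lapply(strsplit(readLines(path), ",", fixed = TRUE),
    as.numeric))
}

#' Write extraction outputs to a directory
#'
#' Writes the artifacts of a channel-correlation extraction as plain text:
#' `y.csv` (the common component, one value per line), `s_per_channel.csv`
#' (rows = channels), `weights.csv` (m x m, columns ordered by descending
#' eigenvalue) and `metadata.json` (boundaries in Hz, transition parameter,
#' ridge, seed, eigenvalues, the normalizer matrix Q and the package
#' version). Output is byte-stable: identical inputs give identical files.
#'
#' @param component an [ExtractedComponent-class].
#' @param solution the [WeightSolution-class] it came from.
#' @param dir output directory (created if missing).
#' @param boundariesHz detected band boundaries in Hz (for the metadata).
#' @param mu transition parameter used (for the metadata).
#' @param seed the run's seed (for the metadata).
#'
#' @return the directory, invisibly.
#' @export
writeOutputs <- function(component, solution, dir,
                         boundariesHz = numeric(), mu = NA_real_,
                         seed = NA_integer_) {
  stopifnot(is(component, "ExtractedComponent"),
    is(solution, "WeightSolution"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  writeLines(c("y", sprintf("%.17g", component@y)), file.path(dir, "y.csv"))
  .writeMatrixCsv(component@perChannelS, file.path(dir, "s_per_channel.csv"))
  .writeMatrixCsv(solution@W, file.path(dir, "weights.csv"))
  meta <- list(
    boundaries_hz = as.numeric(boundariesHz),
    mu = mu,
    ridge = solution@pencil@ridge,
    seed = seed,
    weight_set_used = component@weightSetUsed,
    eigenvalues = solution@eigenvalues,
    Q = apply(solution@pencil@Q, 1L, identity, simplify = FALSE),
    package_version = as.character(utils::packageVersion("ccca")))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write results of a full pipeline run
#'
#' Convenience wrapper around [writeOutputs()] for a [CCCAResult-class].
#'
#' @param result a [CCCAResult-class].
#' @param dir output directory.
#' @param seed the run's seed, recorded in the metadata.
#' @return the directory, invisibly.
#' @export
writeResult <- function(result, dir, seed = NA_integer_) {
  stopifnot(is(result, "CCCAResult"))
  writeOutputs(result@component, result@solution, dir,
    boundariesHz = result@boundariesHz, mu = result@filterBank@mu,
    seed = seed)
}
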