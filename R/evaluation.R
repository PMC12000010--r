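#' One-sided periodogram power spectrum
#'
#' Magnitude-squared discrete Fourier transform of a (optionally zero-padded)
#' signal on the one-sided frequency grid `[0, fs/2]`. Zero padding refines
#' the grid and is how candidate stimulus frequencies that fall between the
#' natural bin frequencies are resolved.
#'
#' @param signal numeric vector, length >= 8.
#' @param fs sampling rate in Hz.
#' @param nfft transform length (>= `length(signal)`); default the signal
#'   length.
#'
#' @return a [SpectrumEstimate-class].
#' @export
powerSpectrum <- function(signal, fs, nfft = NULL) {
  T <- length(signal)
  if (T < 8L) stop("signal must have at least 8 samples")
  if (is.null(nfft)) nfft <- T
  nfft <- as.integer(nfft)
  if (nfft < T) stop("'nfft' must be at least the signal length")
  x <- c(signal, rep(0, nfft - T))
  half <- nfft %/% 2L + 1L
  p <- (Mod(stats::fft(x))^2 / T)[seq_len(half)]
  new("SpectrumEstimate", freqs = (seq_len(half) - 1L) * fs / nfft,
    power = p, methodParams = list(nfft = nfft, window = "rectangular"))
}

#' Recognize the stimulation frequency from a power spectrum
#'
#' For each candidate frequency, reads the power at the nearest grid point and
#' returns the candidate with the maximal power — the standard argmax rule for
#' SSVEP frequency recognition. Exact ties are broken toward the lower
#' candidate frequency.
#'
#' @param spectrum a [SpectrumEstimate-class].
#' @param candidates numeric vector of candidate frequencies in Hz, all
#'   within the spectrum's frequency range.
#'
#' @return the recognized candidate frequency (Hz).
#' @export
recognizeFrequency <- function(spectrum, candidates) {
  stopifnot(is(spectrum, "SpectrumEstimate"))
  if (length(candidates) == 0L) stop("'candidates' must be non-empty")
  f <- spectrum@freqs
  if (any(candidates < min(f)) || any(candidates > max(f)))
    stop("candidate frequency outside the spectrum's range")
  ord <- order(candidates)
  cand <- candidates[ord]
  p <- vapply(cand, function(cf) spectrum@power[which.min(abs(f - cf))],
    numeric(1))
  cand[which.max(p)]   # which.max takes the first maximum = lowest frequency
}

#' Superposition average of repeated trials
#'
#' Element-wise mean over trials: the classical way to raise the
#' signal-to-noise ratio of an event-related response, and the source of the
#' reference waveform extracted components are compared against.
#'
#' @param trials list of equal-length numeric vectors (>= 1 trial).
#' @return numeric vector, the mean waveform.
#' @export
averageReference <- function(trials) {
  if (!is.list(trials) || length(trials) < 1L)
    stop("'trials' must be a non-empty list of vectors")
  len <- lengths(trials)
  if (any(len != len[1L]))
    stop("trial length mismatch: ", paste(unique(len), collapse = " vs "))
  Reduce(`+`, trials) / length(trials)
}

#' Waveform similarity
#'
#' Pearson correlation between an extracted waveform and a reference waveform
#' after mean removal — the judgment criterion for comparing extraction
#' methods against the superposition-averaged reference.
#'
#' @param extracted,reference equal-length numeric vectors (length >= 3),
#'   both non-constant.
#' @return correlation in `[-1, 1]`.
#' @export
similarity <- function(extracted, reference) {
  if (length(extracted) != length(reference))
    stop("'extracted' and 'reference' must have equal length")
  if (length(extracted) < 3L) stop("need at least 3 samples")
  if (stats::sd(extracted) == 0 || stats::sd(reference) == 0)
    stop("similarity is undefined for a constant input")
  stats::cor(extracted, reference)
}

#' Packaged SSVEP recognition-accuracy table
#'
#' Loads the packaged per-subject SSVEP frequency-recognition accuracy table
#' (34 subjects, columns `subject`, `pca`, `ica`, `ccca`, accuracies in
#' `[0, 1]`) used by the bookkeeping operations [bestMethodCount()] and
#' [accuracyDifference()].
#'
#' @return a data.frame.
#' @export
ssvepAccuracyTable <- function() {
  path <- system.file("extdata", "table1_ssvep_accuracy.csv",
    package = "ccca", mustWork = TRUE)
  readRecognitionTable(path)
}

#' Read a recognition-accuracy table
#'
#' @param path CSV file with columns `subject`, `pca`, `ica`, `ccca`.
#' @return a validated data.frame.
#' @export
readRecognitionTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validateRecognitionTable(tab)
  tab
}

.validateRecognitionTable <- function(tab) {
  need <- c("subject", "pca", "ica", "ccca")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  acc <- as.matrix(tab[, c("pca", "ica", "ccca")])
  if (any(is.na(acc)))
    stop("missing method accuracy for subject(s): ",
      paste(tab$subject[apply(is.na(acc), 1L, any)], collapse = ", "))
  if (any(acc < 0 | acc > 1))
    stop("accuracies must lie in [0, 1]")
  if (anyDuplicated(tab$subject))
    stop("duplicated subject id(s)")
  invisible(TRUE)
}

#' Count subjects for which the channel-correlation method is best
#'
#' Counts the subjects whose `ccca` accuracy is at least as high as both
#' comparators (`ccca >= max(pca, ica)`); ties count in favor of the
#' channel-correlation method, matching how the packaged table marks best
#' methods (one marked subject is tied with ICA).
#'
#' @param table data.frame with columns `subject`, `pca`, `ica`, `ccca`.
#' @return integer count.
#' @export
bestMethodCount <- function(table) {
  .validateRecognitionTable(table)
  sum(table$ccca >= pmax(table$pca, table$ica))
}

#' Accuracy difference between two methods, in percentage points
#'
#' @param table data.frame with columns `subject`, `pca`, `ica`, `ccca`.
#' @param subject subject identifier (matched against `table$subject`).
#' @param methodA,methodB method names among `"pca"`, `"ica"`, `"ccca"`.
#' @return `(accuracy_A - accuracy_B) * 100`, rounded to 2 decimals.
#' @export
accuracyDifference <- function(table, subject, methodA, methodB) {
  .validateRecognitionTable(table)
  row <- which(table$subject == subject)
  if (length(row) != 1L) stop("unknown subject: ", subject)
  for (m in c(methodA, methodB))
    if (!m %in% c("pca", "ica", "ccca")) stop("unknown method: ", m)
  round((table[[methodA]][row] - table[[methodB]][row]) * 100, 2)
}

setMethod("show", "SpectrumEstimate", function(object) {
  cat(sprintf("SpectrumEstimate: %d frequencies over [%.3g, %.3g] Hz, peak at %.3g Hz\n",
    length(object@freqs), min(object@freqs), max(object@freqs),
    object@freqs[which.max(object@power)]))
})
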