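#' Meyer auxiliary polynomial
#'
#' The smooth 0-to-1 transition polynomial `beta(x) = x^4 (35 - 84 x + 70 x^2 -
#' 20 x^3)` that shapes the filter roll-offs. It satisfies `beta(0) = 0`,
#' `beta(1) = 1` and the symmetry `beta(x) + beta(1 - x) = 1`, which is what
#' makes the cosine/sine transitions of adjacent filters square-sum to one.
#' Inputs outside `[0, 1]` are clamped (0 below, 1 above), matching the
#' piecewise use inside the filter definitions. Note the second coefficient is
#' the standard Meyer value 84: any other value breaks `beta(1) = 1` and with
#' it the tight-frame property.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length, values in `[0, 1]`.
#' @examples
#' meyerBeta(c(0, 0.5, 1))
#' @export
meyerBeta <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^4 * (35 - 84 * x + 70 * x^2 - 20 * x^3)
}

#' Detect spectral band boundaries
#'
#' Segments the normalized frequency axis `[0, pi]` into `nBands` bands from a
#' magnitude spectrum: the spectrum is lightly smoothed with a moving average,
#' its `nBands` largest local maxima are retained, and one boundary is placed
#' at the global minimum of the smoothed spectrum between each pair of
#' consecutive retained maxima. If fewer than `nBands` local maxima exist the
#' axis is split into `nBands` equal-width bands and a warning is emitted.
#'
#' @param magnitudeSpectrum nonnegative numeric vector sampled on a uniform
#'   grid over `[0, pi]` (first point at 0, last at pi).
#' @param nBands number of bands N (>= 1); N - 1 boundaries are returned.
#' @param smoothSpan odd moving-average window length; default scales with the
#'   grid (about 2 percent of its length, at least 3).
#'
#' @return numeric vector of N - 1 strictly increasing normalized boundary
#'   frequencies in (0, pi); `numeric(0)` when `nBands = 1`.
#' @seealso [ewtFilterBank()]
#' @export
detectBoundaries <- function(magnitudeSpectrum, nBands,
                             smoothSpan = NULL) {
  nBands <- as.integer(nBands)
  L <- length(magnitudeSpectrum)
  if (nBands < 1L) stop("'nBands' must be >= 1")
  if (L < 2L * nBands) stop("spectrum too short for ", nBands, " bands")
  if (any(magnitudeSpectrum < 0)) stop("magnitude spectrum must be nonnegative")
  if (nBands == 1L) return(numeric(0))
  grid <- seq(0, pi, length.out = L)
  if (is.null(smoothSpan)) smoothSpan <- max(3L, 2L * (L %/% 100L) + 1L)
  sm <- .movingAverage(magnitudeSpectrum, smoothSpan)
  # interior local maxima; >= on the left tolerates flat-topped peaks
  idx <- 2:(L - 1L)
  isMax <- sm[idx] >= sm[idx - 1L] & sm[idx] > sm[idx + 1L]
  peaks <- idx[isMax]
  if (length(peaks) < nBands) {
    warning("fewer than ", nBands,
      " local maxima found; falling back to equal-width bands")
    return(pi * seq_len(nBands - 1L) / nBands)
  }
  peaks <- sort(peaks[order(sm[peaks], decreasing = TRUE)][seq_len(nBands)])
  vapply(seq_len(nBands - 1L), function(i) {
    seg <- (peaks[i] + 1L):(peaks[i + 1L] - 1L)
    grid[seg[which.min(sm[seg])]]
  }, numeric(1))
}

.movingAverage <- function(x, span) {
  span <- min(span, length(x))
  if (span %% 2L == 0L) span <- span - 1L
  if (span < 3L) return(x)
  half <- span %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / span, span), sides = 2L))[
    (half + 1L):(half + length(x))]
}

# Evaluate the N filter magnitude responses at |w| values (normalized axis).
# Row 1 is the scaling filter, rows 2..N the wavelet filters; the last wavelet
# is flat up to pi. 'boundaries'/'taus' have length N - 1.
.ewtEvalFilters <- function(boundaries, taus, wabs) {
  N <- length(boundaries) + 1L
  out <- matrix(0, nrow = N, ncol = length(wabs))
  if (N == 1L) {
    out[1L, ] <- 1
    return(out)
  }
  trans <- function(w, wn, tn) meyerBeta((w - wn + tn) / (2 * tn))
  w1 <- boundaries[1L]; t1 <- taus[1L]
  out[1L, wabs <= w1 - t1] <- 1
  inT <- wabs > w1 - t1 & wabs < w1 + t1
  out[1L, inT] <- cos(pi / 2 * trans(wabs[inT], w1, t1))
  for (n in seq_len(N - 1L)) {
    wn <- boundaries[n]; tn <- taus[n]
    upper <- if (n < N - 1L) boundaries[n + 1L] - taus[n + 1L] else pi
    out[n + 1L, wabs >= wn + tn & wabs <= upper] <- 1
    inLo <- wabs > wn - tn & wabs < wn + tn
    out[n + 1L, inLo] <- sin(pi / 2 * trans(wabs[inLo], wn, tn))
    if (n < N - 1L) {
      wu <- boundaries[n + 1L]; tu <- taus[n + 1L]
      inHi <- wabs > wu - tu & wabs < wu + tu
      out[n + 1L, inHi] <- cos(pi / 2 * trans(wabs[inHi], wu, tu))
    }
  }
  out
}

#' Build an empirical wavelet filter bank
#'
#' Constructs Meyer-type scaling and wavelet filters on the normalized
#' frequency axis from a set of band boundaries. Around each boundary `w_n`
#' the filters cross over a transition zone of half-width `tau_n = mu * w_n`
#' using cosine/sine roll-offs shaped by [meyerBeta()], so the squared
#' magnitude responses sum to exactly one at every frequency (tight frame).
#'
#' @param boundaries strictly increasing normalized boundary frequencies in
#'   (0, pi) (length N - 1 for N bands); `numeric(0)` gives the trivial
#'   single-band (all-pass) bank.
#' @param mu transition parameter in (0, 0.5). The default (`NULL`) uses
#'   `0.25 * min((w_next - w) / (w_next + w))` over consecutive boundary pairs
#'   (with pi appended), which can never produce overlapping transitions.
#' @param gridSize number of points of the tabulated responses over `[0, pi]`.
#'
#' @return an [EWTFilterBank-class].
#' @details `mu` must keep adjacent transition zones disjoint
#'   (`w_n + tau_n < w_{n+1} - tau_{n+1}`, and `w_{N-1} + tau_{N-1} < pi`);
#'   violations are rejected with the offending boundary pair named.
#' @examples
#' fb <- ewtFilterBank(boundaries = pi * c(0.25, 0.5, 0.75))
#' nBands(fb)
#' @export
ewtFilterBank <- function(boundaries, mu = NULL, gridSize = 2048L) {
  boundaries <- as.numeric(boundaries)
  gridSize <- as.integer(gridSize)
  N <- length(boundaries) + 1L
  if (N > 1L) {
    if (any(boundaries <= 0) || any(boundaries >= pi))
      stop("boundaries must lie strictly inside (0, pi)")
    if (is.unsorted(boundaries, strictly = TRUE))
      stop("boundaries must be strictly increasing")
    if (is.null(mu)) {
      ext <- c(boundaries, pi)
      gaps <- diff(ext) / (ext[-length(ext)] + ext[-1L])
      mu <- min(0.25 * min(gaps), 0.499)
    }
    if (mu <= 0 || mu >= 0.5) stop("'mu' must lie in (0, 0.5)")
    taus <- mu * boundaries
    ext <- c(boundaries, pi)
    extT <- c(taus, 0)
    bad <- which(ext[-length(ext)] + extT[-length(extT)] >=
                 ext[-1L] - extT[-1L])
    if (length(bad))
      stop(sprintf(
        "transition zones overlap between boundaries %d and %d (%.4f + %.4f >= %.4f - %.4f); reduce 'mu'",
        bad[1L], bad[1L] + 1L, ext[bad[1L]], extT[bad[1L]],
        ext[bad[1L] + 1L], extT[bad[1L] + 1L]))
  } else {
    if (is.null(mu)) mu <- 0.25
    taus <- numeric(0)
  }
  grid <- seq(0, pi, length.out = gridSize)
  resp <- .ewtEvalFilters(boundaries, taus, grid)
  new("EWTFilterBank", nBands = N, boundaries = boundaries,
    mu = as.numeric(mu), taus = taus, gridSize = gridSize, grid = grid,
    phiHat = resp[1L, ], gammaHats = resp[-1L, , drop = FALSE])
}

#' @rdname accessors
#' @export
setMethod("nBands", "EWTFilterBank", function(x) x@nBands)

#' @rdname accessors
#' @export
setMethod("boundaries", "EWTFilterBank", function(x) x@boundaries)

setMethod("show", "EWTFilterBank", function(object) {
  cat(sprintf("EWTFilterBank: %d band(s), mu = %.4g\n", object@nBands,
    object@mu))
  if (length(object@boundaries))
    cat("  boundaries (x pi):",
      paste(sprintf("%.4f", object@boundaries / pi), collapse = ", "), "\n")
})

#' Empirical wavelet decomposition
#'
#' Decomposes a signal into band-limited components: the spectrum is
#' multiplied by each filter's squared magnitude response (the same real, even
#' filter is applied once as the analysis inner product and once as the
#' synthesis convolution) and inverse-transformed. Because the squared
#' responses form a partition of unity, summing the components restores the
#' signal exactly; see [ewtReconstruct()].
#'
#' Applied to a [MultiChannelRecording-class], every channel is decomposed with
#' the same bank and a list of per-channel decompositions is returned.
#'
#' @param signal numeric vector (length >= 2), or a
#'   [MultiChannelRecording-class].
#' @param filterBank an [EWTFilterBank-class]. Filters are evaluated in closed
#'   form on the signal's own discrete frequency grid, so any signal length is
#'   admissible.
#'
#' @return an [EWTComponents-class] (rows ordered low to high frequency), or a
#'   list of them for a recording.
#' @examples
#' fb <- ewtFilterBank(pi / 2)
#' x <- sin(2 * pi * 5 * seq(0, 1, length.out = 200))
#' dec <- ewtDecompose(x, fb)
#' max(abs(ewtReconstruct(dec) - x))
#' @export
setGeneric("ewtDecompose",
  function(signal, filterBank) standardGeneric("ewtDecompose"))

#' @rdname ewtDecompose
#' @export
setMethod("ewtDecompose", "numeric", function(signal, filterBank) {
  T <- length(signal)
  if (T < 2L) stop("signal must have at least 2 samples")
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  k <- 0:(T - 1L)
  wabs <- 2 * pi * pmin(k, T - k) / T   # two-sided grid folded to [0, pi]
  filt <- .ewtEvalFilters(filterBank@boundaries, filterBank@taus, wabs)
  X <- stats::fft(signal)
  comps <- matrix(0, nrow = filterBank@nBands, ncol = T)
  for (b in seq_len(filterBank@nBands))
    comps[b, ] <- Re(stats::fft(X * filt[b, ]^2, inverse = TRUE)) / T
  new("EWTComponents", components = comps, filterBank = filterBank,
    sourceLength = T)
})

#' @rdname ewtDecompose
#' @export
setMethod("ewtDecompose", "MultiChannelRecording",
  function(signal, filterBank) {
    lapply(seq_len(nrow(signal@data)),
      function(i) ewtDecompose(signal@data[i, ], filterBank))
  })

#' @rdname accessors
#' @export
setMethod("nBands", "EWTComponents", function(x) x@filterBank@nBands)

#' @rdname accessors
#' @export
setMethod("bandComponents", "EWTComponents", function(x) x@components)

setMethod("show", "EWTComponents", function(object) {
  cat(sprintf("EWTComponents: %d band(s) x %d samples\n",
    nrow(object@components), object@sourceLength))
})

#' Reconstruct a signal from its empirical wavelet components
#'
#' Sums the band components. For any admissible filter bank this inverts
#' [ewtDecompose()] exactly (up to floating point), because the squared filter
#' responses sum to one at every frequency.
#'
#' @param components an [EWTComponents-class].
#' @return numeric vector of the original signal length.
#' @export
ewtReconstruct <- function(components) {
  stopifnot(is(components, "EWTComponents"))
  colSums(components@components)
}

# Channel-averaged one-sided magnitude spectrum on a uniform grid over
# [0, pi]; the input to boundary detection so that all channels share a bank.
.channelMeanSpectrum <- function(recording) {
  X <- recording@data
  T <- ncol(X)
  half <- T %/% 2L + 1L
  mags <- abs(t(stats::mvfft(t(X))))[, seq_len(half), drop = FALSE]
  colMeans(mags)
}
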