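#' @import methods
NULL

#' Multi-channel recording
#'
#' Container for a multi-channel time-series recording: a numeric matrix with
#' one row per channel (electrode) and one column per time sample, plus the
#' sampling rate in Hz. Amplitudes are microvolt-scale arbitrary units.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz (positive scalar).
#' @slot channelLabels optional character vector of channel names (length 0 or
#'   `nrow(data)`).
#'
#' @seealso [multiChannelRecording()], [readRecording()]
#' @exportClass MultiChannelRecording
setClass("MultiChannelRecording",
  representation(data = "matrix", fs = "numeric", channelLabels = "character"))

setValidity("MultiChannelRecording", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("'data' must be a numeric matrix")
  if (nrow(d) < 1L) return("at least one channel is required")
  if (ncol(d) < 2L) return("at least two samples are required")
  if (!all(is.finite(d))) return("'data' contains non-finite values")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("'fs' must be a single positive number")
  nl <- length(object@channelLabels)
  if (nl != 0L && nl != nrow(d))
    return("'channelLabels' must be empty or one per channel")
  TRUE
})

#' Empirical wavelet filter bank
#'
#' A Meyer-type filter bank on the normalized frequency axis `[0, pi]`
#' (`w = 2*pi*f/fs` maps Hz to normalized frequency). Band `1` is the scaling
#' (low-pass) filter below the first boundary; bands `2..N` are wavelet
#' band-pass filters between consecutive boundaries, the last one flat up to
#' `pi`. Transitions of half-width `tau_n = mu * w_n` around each boundary use
#' the Meyer auxiliary polynomial, so squared magnitudes sum to one at every
#' frequency (a tight frame: decomposition is exactly invertible by summation).
#'
#' @slot nBands number of bands N (>= 1).
#' @slot boundaries N-1 strictly increasing boundary frequencies in (0, pi).
#' @slot mu transition parameter in (0, 0.5); `tau_n = mu * boundaries[n]`.
#' @slot taus transition half-widths.
#' @slot gridSize number of points of the tabulated responses.
#' @slot grid frequency grid over `[0, pi]` the responses are tabulated on.
#' @slot phiHat tabulated scaling-filter magnitude response.
#' @slot gammaHats `(N-1) x gridSize` matrix of wavelet magnitude responses.
#'
#' @seealso [ewtFilterBank()], [ewtDecompose()]
#' @exportClass EWTFilterBank
setClass("EWTFilterBank",
  representation(nBands = "integer", boundaries = "numeric", mu = "numeric",
    taus = "numeric", gridSize = "integer", grid = "numeric",
    phiHat = "numeric", gammaHats = "matrix"))

setValidity("EWTFilterBank", function(object) {
  n <- object@nBands
  b <- object@boundaries
  if (n < 1L) return("'nBands' must be >= 1")
  if (length(b) != n - 1L) return("need exactly nBands - 1 boundaries")
  if (n > 1L) {
    if (any(b <= 0) || any(b >= pi)) return("boundaries must lie in (0, pi)")
    if (is.unsorted(b, strictly = TRUE))
      return("boundaries must be strictly increasing")
    if (object@mu <= 0 || object@mu >= 0.5)
      return("'mu' must lie in (0, 0.5)")
    lo <- c(b, pi) - c(object@taus, 0)
    hi <- c(0, b) + c(0, object@taus)
    if (any(hi >= lo))
      return("transition zones overlap; reduce 'mu'")
  }
  resp <- rbind(object@phiHat, object@gammaHats)
  if (ncol(resp) != object@gridSize) return("grid/response length mismatch")
  if (any(resp < -1e-12) || any(resp > 1 + 1e-12))
    return("filter responses must lie in [0, 1]")
  part <- colSums(resp^2)
  if (max(abs(part - 1)) > 1e-10)
    return("squared responses do not sum to one on the grid")
  TRUE
})

#' Empirical wavelet decomposition of one signal
#'
#' @slot components numeric matrix, `nBands x T`, band signals ordered from low
#'   to high frequency.
#' @slot filterBank the [EWTFilterBank-class] used.
#' @slot sourceLength length T of the decomposed signal.
#'
#' @seealso [ewtDecompose()], [ewtReconstruct()]
#' @exportClass EWTComponents
setClass("EWTComponents",
  representation(components = "matrix", filterBank = "EWTFilterBank",
    sourceLength = "integer"))

setValidity("EWTComponents", function(object) {
  if (nrow(object@components) != object@filterBank@nBands)
    return("one component row per filter-bank band is required")
  if (ncol(object@components) != object@sourceLength)
    return("component length must equal 'sourceLength'")
  if (!all(is.finite(object@components)))
    return("components contain non-finite values")
  TRUE
})

#' Stack of retained band components, one matrix per channel
#'
#' Element i holds the matrix `F_i` (`m` retained bands x `T` samples) of
#' channel i's band components, each row mean-centered over time. All channels
#' are decomposed with the same filter bank, so band j means the same frequency
#' range in every channel.
#'
#' @slot perChannel list of `n_c` numeric matrices of identical shape `m x T`.
#' @slot bandIndices which filter-bank bands the rows correspond to.
#' @slot fs sampling rate in Hz.
#'
#' @seealso [stackBands()]
#' @exportClass BandStack
setClass("BandStack",
  representation(perChannel = "list", bandIndices = "integer", fs = "numeric"))

setValidity("BandStack", function(object) {
  pc <- object@perChannel
  if (length(pc) < 2L) return("at least two channels are required")
  dims <- vapply(pc, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all per-channel matrices must share one shape")
  if (dims[1, 1] < 1L) return("at least one band is required")
  if (dims[1, 1] != length(object@bandIndices))
    return("'bandIndices' must name every row")
  TRUE
})

#' Covariance pencil (S, Q) of a band stack
#'
#' `S` sums the cross-channel band covariance matrices over all ordered channel
#' pairs (the objective); `Q` sums the within-channel band covariances (the
#' normalizer). The band weights solve the generalized eigenproblem
#' `S w = lambda Q w`. When Q is near-singular a small ridge is added to its
#' diagonal and recorded.
#'
#' @slot S m x m symmetric matrix of summed cross-channel covariances.
#' @slot Q m x m symmetric positive (semi-)definite matrix of summed
#'   within-channel covariances, ridge included.
#' @slot ridge the nonnegative ridge added to Q's diagonal (0 if none).
#'
#' @seealso [computePencil()], [solveWeights()]
#' @exportClass CovariancePencil
setClass("CovariancePencil",
  representation(S = "matrix", Q = "matrix", ridge = "numeric"))

setValidity("CovariancePencil", function(object) {
  S <- object@S; Q <- object@Q
  if (!identical(dim(S), dim(Q)) || nrow(S) != ncol(S))
    return("'S' and 'Q' must be square matrices of one size")
  if (max(abs(S - t(S))) > 1e-12 * max(1, max(abs(S))))
    return("'S' must be symmetric")
  if (max(abs(Q - t(Q))) > 1e-12 * max(1, max(abs(Q))))
    return("'Q' must be symmetric")
  if (object@ridge < 0) return("'ridge' must be nonnegative")
  TRUE
})

#' Band-weight solution of the covariance pencil
#'
#' @slot W m x m matrix whose columns are weight vectors, ordered by descending
#'   eigenvalue and normalized so `t(w) %*% Q %*% w = 1`.
#' @slot eigenvalues generalized eigenvalues, descending.
#' @slot pencil the [CovariancePencil-class] that was solved.
#'
#' @seealso [solveWeights()], [extractComponent()]
#' @exportClass WeightSolution
setClass("WeightSolution",
  representation(W = "matrix", eigenvalues = "numeric",
    pencil = "CovariancePencil"))

setValidity("WeightSolution", function(object) {
  if (ncol(object@W) != length(object@eigenvalues))
    return("one eigenvalue per weight column is required")
  if (is.unsorted(rev(object@eigenvalues)))
    return("eigenvalues must be sorted in descending order")
  TRUE
})

#' Extracted common component
#'
#' @slot y the common feature component (length T): the selected weight column
#'   applied to the channel-averaged band stack.
#' @slot perChannelS `n_c x T` matrix of per-channel feature components `s_i`.
#' @slot weightSetUsed which weight column was applied (1 = leading).
#'
#' @seealso [extractComponent()], [ccca()]
#' @exportClass ExtractedComponent
setClass("ExtractedComponent",
  representation(y = "numeric", perChannelS = "matrix",
    weightSetUsed = "integer"))

setValidity("ExtractedComponent", function(object) {
  if (ncol(object@perChannelS) != length(object@y))
    return("'y' and the rows of 'perChannelS' must share one length")
  TRUE
})

#' Full channel component correlation analysis result
#'
#' Bundles the extracted component with every intermediate artifact of the
#' pipeline so each stage can be inspected.
#'
#' @slot component the [ExtractedComponent-class].
#' @slot solution the [WeightSolution-class] (all weight sets and eigenvalues).
#' @slot stack the centered [BandStack-class] the pencil was computed from.
#' @slot filterBank the shared [EWTFilterBank-class].
#' @slot decompositions list of per-channel [EWTComponents-class].
#' @slot boundariesHz detected band boundaries in Hz.
#' @slot fs sampling rate in Hz.
#'
#' @seealso [ccca()]
#' @exportClass CCCAResult
setClass("CCCAResult",
  representation(component = "ExtractedComponent", solution = "WeightSolution",
    stack = "BandStack", filterBank = "EWTFilterBank",
    decompositions = "list", boundariesHz = "numeric", fs = "numeric"))

#' Baseline (PCA / ICA) extraction result
#'
#' @slot components k x T matrix of extracted source time courses.
#' @slot mixingInfo k x n_c unmixing weights (row i maps channels to source i).
#' @slot methodTag `"pca"` or `"ica"`.
#' @slot selectedIndex which component row is reported as the extract.
#' @slot converged `FALSE` if an iterative fit hit the iteration cap.
#'
#' @seealso [pcaExtract()], [icaExtract()]
#' @exportClass BaselineResult
setClass("BaselineResult",
  representation(components = "matrix", mixingInfo = "matrix",
    methodTag = "character", selectedIndex = "integer",
    converged = "logical"))

setValidity("BaselineResult", function(object) {
  if (!object@methodTag %in% c("pca", "ica"))
    return("'methodTag' must be \"pca\" or \"ica\"")
  if (!all(is.finite(object@components)))
    return("components contain non-finite values")
  if (object@selectedIndex < 1L || object@selectedIndex > nrow(object@components))
    return("'selectedIndex' out of range")
  TRUE
})

#' One-sided power spectrum estimate
#'
#' @slot freqs ascending frequency grid in Hz.
#' @slot power nonnegative periodogram values, one per grid frequency.
#' @slot methodParams list with the transform length and window used.
#'
#' @seealso [powerSpectrum()], [recognizeFrequency()]
#' @exportClass SpectrumEstimate
setClass("SpectrumEstimate",
  representation(freqs = "numeric", power = "numeric", methodParams = "list"))

setValidity("SpectrumEstimate", function(object) {
  if (length(object@freqs) != length(object@power))
    return("'freqs' and 'power' must have equal length")
  if (is.unsorted(object@freqs)) return("'freqs' must be ascending")
  if (any(object@power < 0)) return("'power' must be nonnegative")
  TRUE
})

#' Specification of a synthetic multi-channel trial
#'
#' Describes the generative model `channel_i(t) = gain_i * shared(t) +
#' noise_i(t)`: a shared component common to all channels plus independent
#' per-channel noise scaled to a requested signal-to-noise ratio.
#'
#' @slot nChannels number of channels.
#' @slot fs sampling rate in Hz.
#' @slot duration trial length in seconds.
#' @slot seed RNG seed; generation is fully deterministic given the seed.
#' @slot sharedKind `"erp_bump"`, `"ssvep_tone"` or `"band_noise"`.
#' @slot sharedParams parameters of the shared component (see
#'   [syntheticSpec()]).
#' @slot channelGains positive per-channel multipliers on the shared component.
#' @slot snrDb shared-to-noise power ratio per channel in dB (`Inf` disables
#'   noise).
#' @slot noiseKind `"white"` or `"pink"`.
#'
#' @seealso [syntheticSpec()], [generateTrial()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(nChannels = "integer", fs = "numeric", duration = "numeric",
    seed = "integer", sharedKind = "character", sharedParams = "list",
    channelGains = "numeric", snrDb = "numeric", noiseKind = "character"))

setValidity("SyntheticSpec", function(object) {
  if (object@nChannels < 1L) return("'nChannels' must be >= 1")
  if (object@fs <= 0) return("'fs' must be positive")
  if (object@duration <= 0) return("'duration' must be positive")
  if (!object@sharedKind %in% c("erp_bump", "ssvep_tone", "band_noise"))
    return("unknown 'sharedKind'")
  if (!object@noiseKind %in% c("white", "pink"))
    return("unknown 'noiseKind'")
  if (length(object@channelGains) != object@nChannels)
    return("one gain per channel is required")
  if (any(object@channelGains <= 0)) return("channel gains must be positive")
  if (is.na(object@snrDb)) return("'snrDb' must not be NA")
  TRUE
})

#' Synthetic trial with ground truth
#'
#' @slot recording the generated [MultiChannelRecording-class].
#' @slot truth the clean shared component (length = number of samples).
#' @slot truthBand index of the band of the default equal-split five-band
#'   filter bank expected to carry the shared component (`NA` if not
#'   band-confined).
#'
#' @seealso [generateTrial()]
#' @exportClass SyntheticTrial
setClass("SyntheticTrial",
  representation(recording = "MultiChannelRecording", truth = "numeric",
    truthBand = "integer"))

setValidity("SyntheticTrial", function(object) {
  if (length(object@truth) != ncol(object@recording@data))
    return("'truth' must have one value per sample")
  TRUE
})
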