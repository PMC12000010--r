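#' Stack retained band components across channels
#'
#' Collects, for every channel, the selected rows of its empirical wavelet
#' decomposition into a matrix `F_i` (m retained bands x T samples) and
#' mean-centers each row over time. All channels must have been decomposed
#' with the same filter bank so that band j denotes one frequency range in
#' every channel.
#'
#' @param decompositions list of per-channel [EWTComponents-class], e.g. from
#'   `ewtDecompose(recording, bank)`.
#' @param bandIndices which bands (rows, 1 = lowest frequency) to retain.
#' @param fs sampling rate in Hz (carried for downstream spectra).
#'
#' @return a [BandStack-class].
#' @export
stackBands <- function(decompositions, bandIndices, fs = NA_real_) {
  if (length(decompositions) < 2L)
    stop("at least two channels are required")
  if (!all(vapply(decompositions, is, logical(1), "EWTComponents")))
    stop("'decompositions' must be a list of EWTComponents")
  dims <- vapply(decompositions, function(d) dim(d@components), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("channel decompositions differ in shape; use one filter bank")
  bandIndices <- as.integer(bandIndices)
  nb <- dims[1, 1]
  bad <- bandIndices[bandIndices < 1L | bandIndices > nb]
  if (length(bad))
    stop("band index out of range: ", paste(bad, collapse = ", "),
      " (bank has ", nb, " bands)")
  perChannel <- lapply(decompositions, function(d) {
    F <- d@components[bandIndices, , drop = FALSE]
    F - rowMeans(F)
  })
  new("BandStack", perChannel = perChannel, bandIndices = bandIndices,
    fs = as.numeric(fs))
}

#' @rdname accessors
#' @export
setMethod("nChannels", "BandStack", function(x) length(x@perChannel))

#' @rdname accessors
#' @export
setMethod("nBands", "BandStack", function(x) nrow(x@perChannel[[1L]]))

#' @rdname accessors
#' @export
setMethod("bandComponents", "BandStack", function(x) x@perChannel)

setMethod("show", "BandStack", function(object) {
  cat(sprintf("BandStack: %d channel(s), %d band(s) x %d samples\n",
    length(object@perChannel), nrow(object@perChannel[[1L]]),
    ncol(object@perChannel[[1L]])))
  cat("  bands retained:", paste(object@bandIndices, collapse = ", "), "\n")
})

#' Compute the covariance pencil of a band stack
#'
#' Forms the two m x m matrices the band-weight problem is built on:
#' `S = sum over ordered channel pairs k != l of cov(F_k, F_l)` (entry (g, h)
#' is the sample covariance of band g in channel k with band h in channel l),
#' the summed cross-channel covariance whose quadratic form `t(w) S w` the
#' weights maximize; and `Q = sum over channels of cov(F_i, F_i)`, the summed
#' within-channel covariance that normalizes the solution via
#' `t(w) Q w = 1`. Sample covariances use mean removal and denominator T - 1.
#' S is symmetrized as `(S + t(S)) / 2` to remove floating-point asymmetry.
#' If Q's smallest eigenvalue is below `1e-10` of its largest, a ridge of
#' `1e-8 * trace(Q) / m` is added to Q's diagonal and recorded.
#'
#' @param stack a [BandStack-class] with at least two channels.
#' @return a [CovariancePencil-class].
#' @export
computePencil <- function(stack) {
  stopifnot(is(stack, "BandStack"))
  pc <- stack@perChannel
  nc <- length(pc)
  m <- nrow(pc[[1L]])
  T <- ncol(pc[[1L]])
  if (T <= m) stop("need more samples than bands (T > m)")
  auto <- lapply(pc, function(F) stats::cov(t(F)))
  zeroVar <- vapply(auto, function(C) diag(C) < .Machine$double.eps,
    logical(m))
  zeroVar <- matrix(zeroVar, nrow = m)
  if (any(apply(zeroVar, 2, all)))
    stop("a channel has only zero-variance bands after centering")
  if (any(zeroVar))
    warning("zero-variance band(s) after centering in ",
      sum(apply(zeroVar, 2, any)), " channel(s)")
  Q <- Reduce(`+`, auto)
  # sum_{k,l} cov(F_k, F_l) = cov(sum_k F_k); subtracting the within-channel
  # part leaves the sum over ordered pairs k != l
  sumF <- Reduce(`+`, pc)
  S <- stats::cov(t(sumF)) - Q
  S <- (S + t(S)) / 2
  Q <- (Q + t(Q)) / 2
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  ridge <- 0
  if (min(ev) < 1e-10 * max(ev)) {
    ridge <- 1e-8 * sum(diag(Q)) / m
    Q <- Q + diag(ridge, m)
  }
  new("CovariancePencil", S = S, Q = Q, ridge = ridge)
}

#' Solve the band-weight generalized eigenproblem
#'
#' Solves `S w = lambda Q w` for the symmetric-definite pencil of
#' [computePencil()]. Q is Cholesky-factored (`Q = t(R) R`) and the problem
#' reduced to an ordinary symmetric eigenproblem for `R^-T S R^-1`; back
#' transformation makes every column satisfy `t(w) Q w = 1` exactly. Columns
#' are ordered by descending eigenvalue — the leading column maximizes the
#' Rayleigh quotient `t(w) S w / t(w) Q w`, i.e. the summed cross-channel
#' covariance at unit total variance. Each column's sign is fixed so its
#' largest-magnitude entry is positive (generalized eigenvectors are
#' sign-ambiguous).
#'
#' @param pencil a [CovariancePencil-class].
#' @return a [WeightSolution-class].
#' @export
solveWeights <- function(pencil) {
  stopifnot(is(pencil, "CovariancePencil"))
  S <- pencil@S; Q <- pencil@Q
  if (!all(is.finite(S)) || !all(is.finite(Q)))
    stop("pencil matrices contain non-finite entries")
  m <- nrow(S)
  R <- tryCatch(chol(Q),
    error = function(e) stop("Q is not positive definite: ",
      conditionMessage(e)))
  Ri <- backsolve(R, diag(m))
  M <- crossprod(Ri, S %*% Ri)
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)   # values already descending
  W <- Ri %*% es$vectors
  for (j in seq_len(m)) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  new("WeightSolution", W = W, eigenvalues = es$values, pencil = pencil)
}

#' @rdname accessors
#' @export
setMethod("weightMatrix", "WeightSolution", function(x) x@W)

#' @rdname accessors
#' @export
setMethod("eigenvalues", "WeightSolution", function(x) x@eigenvalues)

setMethod("show", "WeightSolution", function(object) {
  cat(sprintf("WeightSolution: %d weight set(s)\n", ncol(object@W)))
  cat("  eigenvalues:",
    paste(sprintf("%.4g", object@eigenvalues), collapse = ", "), "\n")
  cat("  leading weights:",
    paste(sprintf("%.4f", object@W[, 1L]), collapse = ", "), "\n")
})

#' Extract the common component with a weight set
#'
#' Applies one weight column to the channel-averaged band stack to obtain the
#' common feature component `y = t(w) %*% mean_i(F_i)`, and to each channel's
#' stack for the per-channel components `s_i = t(w) %*% F_i`. The leading
#' weight set (default) carries the largest summed cross-channel covariance.
#' The overall sign is chosen so that `y` correlates nonnegatively with the
#' reference (by default the channel-averaged band-limited signal; pass the
#' channel-averaged raw recording for the usual convention).
#'
#' @param solution a [WeightSolution-class].
#' @param stack the [BandStack-class] the solution was computed from.
#' @param weightSet which weight column to use (1 = leading).
#' @param reference optional numeric vector (length T) used only to fix the
#'   sign of the output.
#'
#' @return an [ExtractedComponent-class].
#' @export
extractComponent <- function(solution, stack, weightSet = 1L,
                             reference = NULL) {
  stopifnot(is(solution, "WeightSolution"), is(stack, "BandStack"))
  m <- ncol(solution@W)
  weightSet <- as.integer(weightSet)
  if (weightSet < 1L || weightSet > m)
    stop("'weightSet' must be between 1 and ", m)
  w <- solution@W[, weightSet]
  pc <- stack@perChannel
  meanF <- Reduce(`+`, pc) / length(pc)
  y <- as.numeric(crossprod(w, meanF))
  s <- t(vapply(pc, function(F) as.numeric(crossprod(w, F)),
    numeric(ncol(meanF))))
  if (is.null(reference)) reference <- colSums(meanF)
  if (length(reference) == length(y) &&
      stats::sd(reference) > 0 && stats::sd(y) > 0 &&
      stats::cor(y, reference) < 0) {
    y <- -y
    s <- -s
  }
  new("ExtractedComponent", y = y, perChannelS = s,
    weightSetUsed = weightSet)
}

#' @rdname accessors
#' @export
setMethod("commonComponent", "ExtractedComponent", function(x) x@y)

#' @rdname accessors
#' @export
setMethod("channelComponents", "ExtractedComponent",
  function(x) x@perChannelS)

setMethod("show", "ExtractedComponent", function(object) {
  cat(sprintf(
    "ExtractedComponent: %d samples, %d channel component(s), weight set %d\n",
    length(object@y), nrow(object@perChannelS), object@weightSetUsed))
})

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("in stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Channel component correlation analysis
#'
#' Runs the full extraction pipeline on a multi-channel recording: detect band
#' boundaries on the channel-averaged magnitude spectrum, build one shared
#' empirical wavelet filter bank, decompose every channel, stack the retained
#' bands, form the covariance pencil, solve the generalized eigenproblem for
#' the band weights, and extract the common component with the leading weight
#' set. Every intermediate artifact is kept on the returned object.
#'
#' @param recording a [MultiChannelRecording-class] with at least two
#'   channels.
#' @param nBands number of empirical wavelet bands N (default 5).
#' @param bandIndices which bands to retain for the analysis (1 = lowest
#'   frequency). The default keeps the three lowest-frequency bands of a
#'   five-band decomposition — the usual choice for event-related potentials,
#'   whose energy is low-frequency; pass `seq_len(nBands)` to analyze the full
#'   spectrum (e.g. for SSVEP).
#' @param mu transition parameter for [ewtFilterBank()] (`NULL` = automatic).
#' @param boundaries optional explicit normalized boundaries, bypassing
#'   detection.
#' @param weightSet which weight set to extract with (1 = leading).
#' @param gridSize tabulation grid size for the filter bank.
#'
#' @return a [CCCAResult-class]; see [commonComponent()], [weightMatrix()],
#'   [eigenvalues()].
#' @examples
#' tr <- generateTrial(syntheticSpec(sharedKind = "ssvep_tone", seed = 1))
#' fit <- ccca(trialRecording(tr), nBands = 5, bandIndices = 1:5)
#' fit
#' @export
ccca <- function(recording, nBands = 5L, bandIndices = NULL, mu = NULL,
                 boundaries = NULL, weightSet = 1L, gridSize = 2048L) {
  stopifnot(is(recording, "MultiChannelRecording"))
  if (nrow(recording@data) < 2L)
    stop("at least two channels are required: ",
      "cross-channel covariance is undefined for a single channel")
  nBands <- as.integer(nBands)
  if (is.null(boundaries)) {
    spec <- .stage("spectrum", .channelMeanSpectrum(recording))
    boundaries <- .stage("boundary detection",
      detectBoundaries(spec, nBands))
  } else {
    nBands <- length(boundaries) + 1L
  }
  bank <- .stage("filter bank", ewtFilterBank(boundaries, mu, gridSize))
  decomp <- .stage("decomposition", ewtDecompose(recording, bank))
  if (is.null(bandIndices)) bandIndices <- seq_len(min(3L, nBands))
  stack <- .stage("band stacking",
    stackBands(decomp, bandIndices, fs = recording@fs))
  pencil <- .stage("covariance pencil", computePencil(stack))
  solution <- .stage("eigensolver", solveWeights(pencil))
  component <- .stage("extraction",
    extractComponent(solution, stack, weightSet = weightSet,
      reference = colMeans(recording@data)))
  new("CCCAResult", component = component, solution = solution,
    stack = stack, filterBank = bank, decompositions = decomp,
    boundariesHz = boundaries * recording@fs / (2 * pi),
    fs = recording@fs)
}

#' @rdname accessors
#' @export
setMethod("commonComponent", "CCCAResult",
  function(x) x@component@y)

#' @rdname accessors
#' @export
setMethod("channelComponents", "CCCAResult",
  function(x) x@component@perChannelS)

#' @rdname accessors
#' @export
setMethod("weightMatrix", "CCCAResult", function(x) x@solution@W)

#' @rdname accessors
#' @export
setMethod("eigenvalues", "CCCAResult", function(x) x@solution@eigenvalues)

#' @rdname accessors
#' @export
setMethod("boundaries", "CCCAResult", function(x) x@boundariesHz)

setMethod("show", "CCCAResult", function(object) {
  w1 <- object@solution@W[, 1L]
  cat(sprintf("CCCAResult: %d channel(s), %d band(s) retained of %d\n",
    length(object@stack@perChannel), nrow(object@stack@perChannel[[1L]]),
    object@filterBank@nBands))
  cat("  boundaries (Hz):",
    paste(sprintf("%.2f", object@boundariesHz), collapse = ", "), "\n")
  cat("  eigenvalues:",
    paste(sprintf("%.4g", object@solution@eigenvalues), collapse = ", "),
    "\n")
  cat(sprintf("  dominant band (|w1|): %d of bands {%s}\n",
    object@stack@bandIndices[which.max(abs(w1))],
    paste(object@stack@bandIndices, collapse = ", ")))
  if (object@solution@pencil@ridge > 0)
    cat(sprintf("  ridge applied to Q: %.3g\n",
      object@solution@pencil@ridge))
})
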