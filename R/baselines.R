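# Run expr with a temporarily seeded RNG, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Principal component extraction
#'
#' Mean-centers every channel, eigendecomposes the channel covariance matrix
#' and returns the top-k principal component time courses, ordered by
#' descending explained variance and sign-aligned to the channel-averaged
#' signal. Serves as one of the two standard comparators for common-component
#' extraction.
#'
#' @param recording a [MultiChannelRecording-class] with >= 2 channels.
#' @param k number of components to return (default 1).
#'
#' @return a [BaselineResult-class]; `mixingInfo` holds the eigenvector rows
#'   mapping channels to components, and the component variances (the channel
#'   covariance eigenvalues) are attached as `attr(components, "variances")`.
#' @details If the channel covariance is rank deficient (eigenvalues below
#'   `1e-12` of the largest), fewer than `k` components are returned with a
#'   warning.
#' @export
pcaExtract <- function(recording, k = 1L) {
  stopifnot(is(recording, "MultiChannelRecording"))
  X <- recording@data
  if (nrow(X) < 2L) stop("PCA needs at least two channels")
  k <- as.integer(k)
  if (k < 1L || k > nrow(X)) stop("'k' must be between 1 and the channel count")
  Xc <- X - rowMeans(X)
  C <- stats::cov(t(Xc))
  es <- eigen(C, symmetric = TRUE)
  rank <- sum(es$values > 1e-12 * max(es$values, 0))
  if (k > rank) {
    warning("rank-deficient input: returning ", rank,
      " component(s) instead of ", k)
    k <- rank
  }
  V <- es$vectors[, seq_len(k), drop = FALSE]
  comps <- t(V) %*% Xc
  ref <- colMeans(Xc)
  for (j in seq_len(k)) {
    if (stats::sd(comps[j, ]) > 0 && stats::sd(ref) > 0 &&
        stats::cor(comps[j, ], ref) < 0) {
      comps[j, ] <- -comps[j, ]
      V[, j] <- -V[, j]
    }
  }
  res <- new("BaselineResult", components = comps, mixingInfo = t(V),
    methodTag = "pca", selectedIndex = 1L, converged = TRUE)
  attr(res@components, "variances") <- es$values[seq_len(k)]
  res
}

#' Independent component extraction
#'
#' Whitens the channels and runs a deflationary fixed-point ICA that maximizes
#' negentropy with the log-cosh contrast (`g(u) = tanh(u)`), with a fixed seed
#' for the random initial directions, bounded iterations and convergence
#' tolerance `1e-6`. ICA returns its components in no meaningful order and
#' with no built-in notion of which one is "the" signal, so a selection rule
#' is applied afterwards: the component with the largest absolute correlation
#' to `reference` (or to the channel-averaged signal when no reference is
#' given) becomes `selectedIndex`. The selection rule is an evaluation
#' convenience of this package, not part of ICA itself.
#'
#' @param recording a [MultiChannelRecording-class] with >= 2 channels.
#' @param k number of independent components (default: number of channels).
#' @param reference optional numeric vector used to pick `selectedIndex`.
#' @param seed RNG seed for the initial directions.
#' @param maxit iteration cap per component.
#' @param tol convergence tolerance on the direction update.
#'
#' @return a [BaselineResult-class]; `converged` is `FALSE` when any
#'   component hit the iteration cap (the best iterate is returned).
#' @export
icaExtract <- function(recording, k = NULL, reference = NULL, seed = 1L,
                       maxit = 500L, tol = 1e-6) {
  stopifnot(is(recording, "MultiChannelRecording"))
  X <- recording@data
  nc <- nrow(X)
  T <- ncol(X)
  if (nc < 2L) stop("ICA needs at least two channels")
  if (is.null(k)) k <- nc
  k <- as.integer(k)
  if (k < 1L || k > nc) stop("'k' must be between 1 and the channel count")
  Xc <- X - rowMeans(X)
  C <- stats::cov(t(Xc))
  es <- eigen(C, symmetric = TRUE)
  pos <- es$values > 1e-12 * max(es$values, 0)
  if (sum(pos) < k) stop("input rank is below 'k'; reduce 'k'")
  Kw <- diag(1 / sqrt(es$values[seq_len(k)]), k) %*%
    t(es$vectors[, seq_len(k), drop = FALSE])
  Z <- Kw %*% Xc               # whitened: cov(t(Z)) = I
  B <- matrix(0, k, k)
  converged <- TRUE
  .withSeed(seed, {
    for (p in seq_len(k)) {
      w <- stats::rnorm(k)
      w <- w / sqrt(sum(w^2))
      ok <- FALSE
      for (it in seq_len(maxit)) {
        wx <- drop(crossprod(w, Z))
        g <- tanh(wx)
        wNew <- drop(Z %*% g) / T - mean(1 - g^2) * w
        if (p > 1L) {
          Bp <- B[, seq_len(p - 1L), drop = FALSE]
          wNew <- wNew - Bp %*% crossprod(Bp, wNew)
        }
        wNew <- wNew / sqrt(sum(wNew^2))
        if (abs(abs(sum(wNew * w)) - 1) < tol) {
          w <- wNew
          ok <- TRUE
          break
        }
        w <- wNew
      }
      if (!ok) converged <- FALSE
      B[, p] <- w
    }
  })
  comps <- t(B) %*% Z          # k x T independent sources
  unmix <- t(B) %*% Kw         # k x nc
  if (is.null(reference)) reference <- colMeans(Xc)
  sel <- 1L
  if (length(reference) == T && stats::sd(reference) > 0) {
    cors <- apply(comps, 1L, function(s)
      if (stats::sd(s) > 0) abs(stats::cor(s, reference)) else 0)
    sel <- which.max(cors)
    for (j in seq_len(k)) {
      if (stats::sd(comps[j, ]) > 0 &&
          stats::cor(comps[j, ], reference) < 0) {
        comps[j, ] <- -comps[j, ]
        unmix[j, ] <- -unmix[j, ]
      }
    }
  }
  new("BaselineResult", components = comps, mixingInfo = unmix,
    methodTag = "ica", selectedIndex = as.integer(sel),
    converged = converged)
}

#' @describeIn pcaExtract the reported component time course (the
#'   `selectedIndex` row).
#' @param x a `BaselineResult`.
#' @export
setMethod("commonComponent", "BaselineResult",
  function(x) x@components[x@selectedIndex, ])

setMethod("show", "BaselineResult", function(object) {
  cat(sprintf("BaselineResult (%s): %d component(s) x %d samples, selected %d%s\n",
    object@methodTag, nrow(object@components), ncol(object@components),
    object@selectedIndex,
    if (object@converged) "" else " [not converged]"))
})
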