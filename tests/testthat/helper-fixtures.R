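# Random strictly-separated boundary sets for which the automatic 'mu' is
# always admissible (every gap, including to 0 and pi, at least 0.05*pi).
randomAdmissibleBoundaries <- function(n) {
  repeat {
    b <- sort(stats::runif(n, 0.1 * pi, 0.9 * pi))
    if (all(diff(c(0, b, pi)) > 0.05 * pi)) return(b)
  }
}

# Random symmetric-definite pencil: S symmetric, Q symmetric positive definite.
randomPencil <- function(m) {
  A <- matrix(stats::rnorm(m * m), m)
  S <- (A + t(A)) / 2
  B <- matrix(stats::rnorm(m * m), m)
  Q <- crossprod(B) + diag(0.5, m)
  new("CovariancePencil", S = S, Q = Q, ridge = 0)
}

# Brute-force Rayleigh-quotient maximum over nDir random Q-normalized
# directions -- the independent oracle for the eigensolver.
bruteForceRayleigh <- function(S, Q, nDir = 1e5) {
  V <- matrix(stats::rnorm(nrow(S) * nDir), nrow = nrow(S))
  qn <- sqrt(colSums(V * (Q %*% V)))
  V <- sweep(V, 2L, qn, "/")
  max(colSums(V * (S %*% V)))
}

# The equal-split five-band bank matching the synthetic generator's
# 'truthBand' convention.
defaultFiveBandBank <- function() ewtFilterBank(pi * (1:4) / 5)

rscriptBin <- function() file.path(R.home("bin"), "Rscript")

cliScript <- function() system.file("exec", "ccca.R", package = "ccca")
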