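makeStack <- function(mats, bands = seq_len(nrow(mats[[1]])), fs = 100) {
  fb <- ewtFilterBank(numeric(0))
  # wrap plain matrices as a BandStack through the validated constructor path
  new("BandStack",
    perChannel = lapply(mats, function(F) F - rowMeans(F)),
    bandIndices = as.integer(bands), fs = fs)
}

test_that("band stacking selects, centers and validates", {
  rec <- multiChannelRecording(matrix(rnorm(2 * 300), nrow = 2), fs = 100)
  fb <- ewtFilterBank(pi * (1:4) / 5)
  dec <- ewtDecompose(rec, fb)
  st <- stackBands(dec, c(3, 4, 5), fs = 100)
  expect_equal(nChannels(st), 2L)
  expect_equal(nBands(st), 3L)
  expect_true(all(abs(vapply(bandComponents(st), rowMeans,
    numeric(3))) < 1e-12))
  expect_error(stackBands(dec, c(1, 6)), "6")
  expect_error(stackBands(dec[1], 1:3), "two channels")
})

test_that("a constant band centers to an all-zero row with a warning", {
  F <- rbind(rep(5, 50), rnorm(50))
  st <- makeStack(list(F, F + rnorm(1)))
  expect_true(all(bandComponents(st)[[1]][1, ] == 0))
  expect_warning(computePencil(st), "zero-variance")
})

test_that("identical and sign-flipped channels give the analytic pencils", {
  set.seed(5)
  F <- matrix(rnorm(3 * 200), nrow = 3)
  F <- F - rowMeans(F)
  C <- cov(t(F))
  p <- computePencil(makeStack(list(F, F)))
  expect_equal(p@S, 2 * C, tolerance = 1e-12)
  expect_equal(p@Q, 2 * C, tolerance = 1e-12)
  pNeg <- computePencil(makeStack(list(F, -F)))
  expect_equal(pNeg@S, -pNeg@Q, tolerance = 1e-12)
})

test_that("the pencil matches a direct pairwise-covariance oracle", {
  set.seed(11)
  mats <- replicate(3, matrix(rnorm(2 * 150), nrow = 2), simplify = FALSE)
  st <- makeStack(mats)
  p <- computePencil(st)
  pc <- bandComponents(st)
  Sdirect <- matrix(0, 2, 2)
  Qdirect <- matrix(0, 2, 2)
  for (k in 1:3) for (l in 1:3) {
    Ckl <- cov(t(pc[[k]]), t(pc[[l]]))
    if (k == l) Qdirect <- Qdirect + Ckl else Sdirect <- Sdirect + Ckl
  }
  expect_equal(p@S, (Sdirect + t(Sdirect)) / 2, tolerance = 1e-12)
  expect_equal(p@Q, Qdirect, tolerance = 1e-12)
})

test_that("cross-covariances of independent channels are near zero", {
  set.seed(21)
  mats <- replicate(3, matrix(rnorm(2 * 20000), nrow = 2), simplify = FALSE)
  p <- computePencil(makeStack(mats))
  scale <- sqrt(outer(diag(p@Q), diag(p@Q)))
  expect_true(all(abs(p@S) <= 0.05 * scale))
})

test_that("the eigensolver handles the analytic cases", {
  C <- crossprod(matrix(rnorm(9), 3)) + diag(0.1, 3)
  sol <- solveWeights(new("CovariancePencil", S = C, Q = C, ridge = 0))
  expect_equal(eigenvalues(sol), rep(1, 3), tolerance = 1e-12)
  sol2 <- solveWeights(new("CovariancePencil",
    S = diag(c(1, 0)), Q = diag(2), ridge = 0))
  expect_equal(eigenvalues(sol2), c(1, 0))
  expect_equal(weightMatrix(sol2)[, 1], c(1, 0))
})

test_that("solved weights satisfy the eigen-residual and the constraint", {
  for (s in 1:20) {
    set.seed(200 + s)
    p <- randomPencil(sample(2:6, 1))
    sol <- solveWeights(p)
    m <- ncol(weightMatrix(sol))
    normS <- norm(p@S, "F")
    for (j in seq_len(m)) {
      w <- weightMatrix(sol)[, j]
      lam <- eigenvalues(sol)[j]
      expect_lt(sqrt(sum((p@S %*% w - lam * p@Q %*% w)^2)), 1e-8 * normS)
      expect_equal(drop(crossprod(w, p@Q %*% w)), 1, tolerance = 1e-10)
      i <- which.max(abs(w))
      expect_gt(w[i], 0)
    }
  }
})

test_that("no random direction beats the leading eigenvalue (Rayleigh-Ritz)", {
  set.seed(300)
  p <- randomPencil(4)
  sol <- solveWeights(p)
  V <- matrix(rnorm(4 * 1e4), nrow = 4)
  V <- sweep(V, 2L, sqrt(colSums(V * (p@Q %*% V))), "/")
  expect_lte(max(colSums(V * (p@S %*% V))),
    eigenvalues(sol)[1] + 1e-9)
})

test_that("the leading eigenpair matches brute-force maximization", {
  for (m in c(2L, 3L)) {
    set.seed(400 + m)
    p <- randomPencil(m)
    sol <- solveWeights(p)
    best <- bruteForceRayleigh(p@S, p@Q)
    expect_equal(eigenvalues(sol)[1], best,
      tolerance = 1e-3)
  }
})

test_that("extraction reproduces the unit-variance constraint analytically", {
  set.seed(31)
  for (nc in c(2L, 4L)) {
    f <- matrix(rnorm(120), nrow = 1)
    st <- makeStack(replicate(nc, f, simplify = FALSE))
    sol <- solveWeights(computePencil(st))
    comp <- extractComponent(sol, st)
    expect_equal(var(commonComponent(comp)), 1 / nc, tolerance = 1e-9)
    expect_equal(nrow(channelComponents(comp)), nc)
  }
})

test_that("extraction validates the weight-set index and fixes the sign", {
  set.seed(33)
  mats <- replicate(2, matrix(rnorm(3 * 100), nrow = 3), simplify = FALSE)
  st <- makeStack(mats)
  sol <- solveWeights(computePencil(st))
  expect_error(extractComponent(sol, st, weightSet = 4), "between 1 and 3")
  ref <- rnorm(100)
  comp <- extractComponent(sol, st, reference = ref)
  expect_gte(cor(commonComponent(comp), ref), 0)
})

test_that("uniform channel rescaling leaves weights and eigenvalues alone", {
  set.seed(44)
  mats <- replicate(3, matrix(rnorm(2 * 400), nrow = 2), simplify = FALSE)
  solA <- solveWeights(computePencil(makeStack(mats)))
  solB <- solveWeights(computePencil(makeStack(
    lapply(mats, function(F) 3.7 * F))))
  expect_equal(eigenvalues(solB), eigenvalues(solA), tolerance = 1e-9)
  # Q-normalization scales columns by 1/c; directions are unchanged
  WA <- apply(weightMatrix(solA), 2L, function(w) w / sqrt(sum(w^2)))
  WB <- apply(weightMatrix(solB), 2L, function(w) w / sqrt(sum(w^2)))
  expect_equal(WB, WA, tolerance = 1e-8)
})

test_that("the pipeline rejects single-channel input and names stages", {
  rec1 <- multiChannelRecording(matrix(rnorm(100), nrow = 1), fs = 100)
  expect_error(ccca(rec1), "two channels")
  recBad <- multiChannelRecording(matrix(rnorm(2 * 100), nrow = 2), fs = 100)
  expect_error(ccca(recBad, nBands = 5, bandIndices = c(1, 9)),
    "band stacking")
})

test_that("duplicated channels make the pencil proportional", {
  set.seed(55)
  x <- matrix(rnorm(2 * 500), nrow = 2)
  rec2 <- multiChannelRecording(rbind(x[1, ], x[1, ]), fs = 100)
  fit2 <- ccca(rec2, nBands = 3, bandIndices = 1:3,
    boundaries = pi * c(1, 2) / 3)
  expect_equal(eigenvalues(fit2), rep(1, 3), tolerance = 1e-9)
  # four identical copies: S = (nc^2 - nc) C, Q = nc C, so every
  # eigenvalue equals nc - 1
  rec4 <- multiChannelRecording(x[rep(1, 4), ], fs = 100)
  fit4 <- ccca(rec4, nBands = 3, bandIndices = 1:3,
    boundaries = pi * c(1, 2) / 3)
  expect_equal(eigenvalues(fit4), rep(3, 3), tolerance = 1e-9)
})

test_that("the leading weight set points at the band carrying the shared
          component", {
  fb <- defaultFiveBandBank()
  hits <- 0L
  cors <- numeric(10)
  for (s in 1:10) {
    tr <- generateTrial(syntheticSpec(sharedKind = "band_noise", seed = s))
    rec <- trialRecording(tr)
    st <- stackBands(ewtDecompose(rec, fb), 1:5, fs = samplingRate(rec))
    sol <- solveWeights(computePencil(st))
    if (which.max(abs(weightMatrix(sol)[, 1])) == truthBand(tr))
      hits <- hits + 1L
    comp <- extractComponent(sol, st,
      reference = colMeans(as.matrix(rec)))
    cors[s] <- abs(cor(commonComponent(comp), trialTruth(tr)))
  }
  expect_gte(hits, 9L)
  expect_gte(median(cors), 0.9)
})

test_that("the pipeline recovers an SSVEP tone end to end", {
  tr <- generateTrial(syntheticSpec(sharedKind = "ssvep_tone", seed = 2))
  fit <- ccca(trialRecording(tr), nBands = 5, bandIndices = 1:5)
  ps <- powerSpectrum(commonComponent(fit), samplingRate(trialRecording(tr)),
    nfft = 1000L)
  expect_equal(recognizeFrequency(ps, 8:15), 10)
  # intermediates are retrievable
  expect_s4_class(fit@stack, "BandStack")
  expect_s4_class(fit@solution@pencil, "CovariancePencil")
  expect_length(fit@decompositions, 8L)
})
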