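test_that("generation is bit-deterministic given the seed", {
  sp <- syntheticSpec(sharedKind = "band_noise", seed = 13)
  a <- generateTrial(sp)
  b <- generateTrial(sp)
  expect_identical(as.matrix(trialRecording(a)),
    as.matrix(trialRecording(b)))
  expect_identical(trialTruth(a), trialTruth(b))
  c <- generateTrial(syntheticSpec(sharedKind = "band_noise", seed = 14))
  expect_false(identical(as.matrix(trialRecording(a)),
    as.matrix(trialRecording(c))))
})

test_that("the noise-free limit returns the truth on every channel", {
  tr <- generateTrial(syntheticSpec(nChannels = 4, sharedKind = "erp_bump",
    snrDb = Inf, seed = 1))
  X <- as.matrix(trialRecording(tr))
  for (i in 1:4) expect_equal(X[i, ], trialTruth(tr), tolerance = 1e-14)
  # channel gains scale the shared part
  tr2 <- generateTrial(syntheticSpec(nChannels = 2, sharedKind = "erp_bump",
    snrDb = Inf, channelGains = c(1, 2.5), seed = 1))
  X2 <- as.matrix(trialRecording(tr2))
  expect_equal(X2[2, ], 2.5 * X2[1, ], tolerance = 1e-14)
})

test_that("the realized SNR matches the request within half a dB", {
  for (s in 1:5) {
    tr <- generateTrial(syntheticSpec(sharedKind = "ssvep_tone", snrDb = 0,
      seed = s))
    X <- as.matrix(trialRecording(tr))
    shared <- trialTruth(tr)   # zero phase jitter: shared part == truth
    for (i in seq_len(nrow(X))) {
      noise <- X[i, ] - shared
      snr <- 10 * log10(mean(shared^2) / mean(noise^2))
      expect_lt(abs(snr - 0), 0.5)
    }
  }
})

test_that("zero shared power cannot be scaled to a finite SNR", {
  sp <- syntheticSpec(sharedKind = "erp_bump",
    sharedParams = list(amplitude = 0), snrDb = 0, seed = 1)
  expect_error(generateTrial(sp), "zero power")
})

test_that("the ERP bump is a low-frequency waveform", {
  tr <- generateTrial(syntheticSpec(nChannels = 1, sharedKind = "erp_bump",
    snrDb = Inf, duration = 0.8, seed = 1))
  bump <- trialTruth(tr)
  T <- length(bump)
  f <- pmin(0:(T - 1), T - (0:(T - 1))) * 250 / T
  spec <- Mod(fft(bump))^2
  expect_gte(sum(spec[f <= 8]) / sum(spec), 0.9)
  expect_equal(which.max(bump), which.min(abs((0:(T - 1)) / 250 - 0.4)))
})

test_that("band-limited shared components land in their nominal band", {
  tr <- generateTrial(syntheticSpec(sharedKind = "band_noise", seed = 3))
  expect_equal(truthBand(tr), 3L)
  dec <- ewtDecompose(trialTruth(tr), defaultFiveBandBank())
  energy <- rowSums(bandComponents(dec)^2)
  expect_equal(which.max(energy), 3L)
  expect_gte(energy[3] / sum(energy), 0.99)
  # a passband spanning a band edge is not band-confined
  tr2 <- generateTrial(syntheticSpec(sharedKind = "band_noise",
    sharedParams = list(passband = c(40, 60)), seed = 3))
  expect_true(is.na(truthBand(tr2)))
})

test_that("ERP sessions support both layouts and reject bad jitter", {
  sp <- syntheticSpec(nChannels = 3, sharedKind = "erp_bump", snrDb = Inf,
    duration = 0.8, seed = 5)
  trials <- generateErpSession(4, sp)
  expect_length(trials, 4L)
  expect_identical(as.matrix(trialRecording(trials[[1]])),
    as.matrix(trialRecording(trials[[4]])))   # zero jitter, noise-free

  asChan <- generateErpSession(6, sp, layout = "trials_as_channels")
  expect_s4_class(asChan, "SyntheticTrial")
  expect_equal(nChannels(trialRecording(asChan)), 6L)

  expect_error(generateErpSession(4, sp, latencyJitterSd = 10),
    "outside the epoch")
  expect_error(generateErpSession(0, sp), ">= 1")
  spTone <- syntheticSpec(sharedKind = "ssvep_tone", seed = 1)
  expect_error(generateErpSession(4, spTone), "erp_bump")
})

test_that("averaging jittered noisy trials beats the median single trial", {
  sp <- syntheticSpec(nChannels = 1, sharedKind = "erp_bump", snrDb = -10,
    duration = 0.8, seed = 0)
  wins <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    sp@seed <- r
    trials <- generateErpSession(56, sp, latencyJitterSd = 0.01,
      amplitudeJitterSd = 0.05)
    waves <- lapply(trials, function(tr)
      as.numeric(as.matrix(trialRecording(tr))[1, ]))
    truth <- exp(-((seq_len(length(waves[[1]])) - 1) / 250 - 0.4)^2 /
      (2 * 0.05^2))
    simAvg <- similarity(averageReference(waves), truth)
    simSingle <- vapply(waves, similarity, numeric(1), reference = truth)
    if (simAvg > median(simSingle)) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.95 * reps))
})

test_that("pink noise concentrates power at low frequencies", {
  tr <- generateTrial(syntheticSpec(nChannels = 1, sharedKind = "ssvep_tone",
    snrDb = -20, noiseKind = "pink", seed = 8, duration = 4))
  x <- as.numeric(as.matrix(trialRecording(tr)))
  spec <- Mod(fft(x))^2
  T <- length(x)
  half <- 2:(T %/% 2)
  lowHalf <- half[half <= length(half) / 2]
  highHalf <- half[half > length(half) / 2]
  expect_gt(sum(spec[lowHalf]), 3 * sum(spec[highHalf]))
})

test_that("per-channel phase jitter perturbs channels but not the truth", {
  sp <- syntheticSpec(sharedKind = "ssvep_tone",
    sharedParams = list(phaseJitter = 0.2), snrDb = Inf, seed = 6)
  tr <- generateTrial(sp)
  X <- as.matrix(trialRecording(tr))
  expect_false(identical(X[1, ], X[2, ]))
  # every channel is still the same tone to within a small time shift
  for (i in 1:2) expect_gt(abs(cor(X[i, ], trialTruth(tr))), 0.9)
})
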