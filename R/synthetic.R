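#' Specify a synthetic multi-channel trial
#'
#' Builds the specification of a seeded synthetic EEG-like trial following the
#' generative model `channel_i(t) = gain_i * shared(t) + noise_i(t)`: a shared
#' component common to all channels plus independent per-channel noise scaled
#' to a requested signal-to-noise ratio. Three shared-component families are
#' available:
#'
#' * `"erp_bump"` — a Gaussian-windowed positive deflection mimicking a P300:
#'   `amplitude * exp(-(t - latency)^2 / (2 (width/2)^2))`. Defaults: latency
#'   0.4 s, width 0.1 s, amplitude 1 (low-frequency energy, concentrated
#'   below ~8 Hz).
#' * `"ssvep_tone"` — a sinusoid at `frequency` Hz plus `nHarmonics - 1`
#'   harmonics with amplitudes `1/h`; optional per-channel phase jitter
#'   (`phaseJitter`, radians sd) emulates small propagation differences.
#'   Defaults: frequency 10 Hz, nHarmonics 3, phaseJitter 0.
#' * `"band_noise"` — Gaussian noise band-limited to `passband` Hz (hard
#'   spectral mask, unit RMS). Default passband `c(55, 70)` Hz at
#'   `fs = 250`, i.e. confined to band 3 of the default equal-split
#'   five-band filter bank.
#'
#' @param nChannels number of channels (default 8).
#' @param fs sampling rate in Hz (default 250).
#' @param duration trial length in seconds (default 1).
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @param sharedKind `"erp_bump"`, `"ssvep_tone"` or `"band_noise"`.
#' @param sharedParams named list overriding the kind's defaults (see above).
#' @param channelGains positive per-channel multipliers on the shared
#'   component (default all 1).
#' @param snrDb per-channel shared-to-noise power ratio in dB; `Inf` disables
#'   noise. Default 0 dB.
#' @param noiseKind `"white"` or `"pink"` (`1/f` power) background noise.
#'
#' @return a [SyntheticSpec-class].
#' @seealso [generateTrial()], [generateErpSession()]
#' @export
syntheticSpec <- function(nChannels = 8L, fs = 250, duration = 1,
                          seed = 1L, sharedKind = "erp_bump",
                          sharedParams = list(),
                          channelGains = rep(1, nChannels),
                          snrDb = 0, noiseKind = "white") {
  defaults <- switch(sharedKind,
    erp_bump = list(latency = 0.4, width = 0.1, amplitude = 1),
    ssvep_tone = list(frequency = 10, nHarmonics = 3L, phaseJitter = 0),
    band_noise = list(passband = c(55, 70)),
    stop("unknown 'sharedKind': ", sharedKind))
  sharedParams <- utils::modifyList(defaults, sharedParams)
  if (sharedKind == "ssvep_tone" &&
      fs <= 2 * sharedParams$frequency * sharedParams$nHarmonics)
    stop("'fs' must exceed twice the highest generated harmonic")
  if (sharedKind == "band_noise" && sharedParams$passband[2L] >= fs / 2)
    stop("passband upper edge must be below fs / 2")
  new("SyntheticSpec", nChannels = as.integer(nChannels),
    fs = as.numeric(fs), duration = as.numeric(duration),
    seed = as.integer(seed), sharedKind = sharedKind,
    sharedParams = sharedParams, channelGains = as.numeric(channelGains),
    snrDb = as.numeric(snrDb), noiseKind = noiseKind)
}

# Band index of frequency f under the default equal-split five-band bank
# (band j spans [(j-1) fs/10, j fs/10] Hz).
.defaultBandOf <- function(f, fs) {
  min(5L, as.integer(floor(f / (fs / 10))) + 1L)
}

.truthBandOf <- function(spec) {
  p <- spec@sharedParams
  switch(spec@sharedKind,
    erp_bump = 1L,
    ssvep_tone = .defaultBandOf(p$frequency, spec@fs),
    band_noise = {
      eps <- 1e-9 * spec@fs
      lo <- .defaultBandOf(p$passband[1L] + eps, spec@fs)
      hi <- .defaultBandOf(p$passband[2L] - eps, spec@fs)
      if (lo == hi) lo else NA_integer_
    })
}

.erpBump <- function(t, latency, width, amplitude) {
  amplitude * exp(-((t - latency)^2) / (2 * (width / 2)^2))
}

.bandNoise <- function(T, fs, passband) {
  x <- stats::rnorm(T)
  k <- 0:(T - 1L)
  f <- pmin(k, T - k) * fs / T
  mask <- as.numeric(f >= passband[1L] & f <= passband[2L])
  y <- Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / T
  y / sqrt(mean(y^2))
}

.pinkNoise <- function(T) {
  x <- stats::rnorm(T)
  k <- 0:(T - 1L)
  f <- pmin(k, T - k)
  amp <- ifelse(f == 0, 0, 1 / sqrt(f))   # 1/f power spectral density
  Re(stats::fft(stats::fft(x) * amp, inverse = TRUE)) / T
}

# Generation body; assumes the RNG is already positioned (seeded by
# generateTrial, or streaming inside generateErpSession).
.generateTrialImpl <- function(spec) {
  T <- round(spec@duration * spec@fs)
  t <- (0:(T - 1L)) / spec@fs
  p <- spec@sharedParams
  nch <- spec@nChannels
  sharedPerChannel <- switch(spec@sharedKind,
    erp_bump = {
      bump <- .erpBump(t, p$latency, p$width, p$amplitude)
      list(truth = bump, chans = replicate(nch, bump, simplify = FALSE))
    },
    ssvep_tone = {
      tone <- function(phase) {
        h <- seq_len(p$nHarmonics)
        Reduce(`+`, lapply(h, function(hh)
          sin(2 * pi * hh * p$frequency * t + hh * phase) / hh))
      }
      phases <- if (p$phaseJitter > 0)
        stats::rnorm(nch, 0, p$phaseJitter) else rep(0, nch)
      list(truth = tone(0), chans = lapply(phases, tone))
    },
    band_noise = {
      bn <- .bandNoise(T, spec@fs, p$passband)
      list(truth = bn, chans = replicate(nch, bn, simplify = FALSE))
    })
  data <- matrix(0, nrow = nch, ncol = T)
  for (i in seq_len(nch)) {
    sig <- spec@channelGains[i] * sharedPerChannel$chans[[i]]
    if (is.finite(spec@snrDb)) {
      ps <- mean(sig^2)
      if (ps == 0)
        stop("impossible SNR: the shared component has zero power")
      noise <- if (spec@noiseKind == "white") stats::rnorm(T)
        else .pinkNoise(T)
      noise <- noise * sqrt((ps / 10^(spec@snrDb / 10)) / mean(noise^2))
      sig <- sig + noise
    }
    data[i, ] <- sig
  }
  rec <- multiChannelRecording(data, fs = spec@fs,
    channelLabels = sprintf("ch%02d", seq_len(nch)))
  new("SyntheticTrial", recording = rec, truth = sharedPerChannel$truth,
    truthBand = .truthBandOf(spec))
}

#' Generate one synthetic trial
#'
#' Draws a trial from a [syntheticSpec()]: per-channel copies of the shared
#' component (scaled by the channel gains) plus independent noise scaled to
#' the requested SNR. Fully deterministic given the spec's seed — calling
#' twice with the same spec returns bit-identical data.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [SyntheticTrial-class] carrying the recording, the clean shared
#'   component (`trialTruth`) and the filter-bank band expected to carry it
#'   (`truthBand`).
#' @export
generateTrial <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  .withSeed(spec@seed, .generateTrialImpl(spec))
}

#' Generate a session of repeated event-related trials
#'
#' Generates `nTrials` trials sharing one bump template, with optional
#' per-trial jitter of latency (Gaussian, `latencyJitterSd` seconds) and
#' amplitude (multiplicative, `1 + N(0, amplitudeJitterSd)`). Two layouts
#' support the two multi-trial analyses: `"channels"` keeps each trial a
#' multi-channel recording (a list is returned); `"trials_as_channels"`
#' generates one electrode per trial and stacks the trials as the channels of
#' a single recording, for analyses that treat repeated trials of one
#' electrode as a multi-channel signal.
#'
#' @param nTrials number of trials (>= 1).
#' @param spec a [SyntheticSpec-class] with `sharedKind = "erp_bump"`.
#' @param latencyJitterSd per-trial latency jitter sd in seconds.
#' @param amplitudeJitterSd per-trial relative amplitude jitter sd.
#' @param layout `"channels"` or `"trials_as_channels"`.
#'
#' @return a list of [SyntheticTrial-class] (layout `"channels"`) or a single
#'   [SyntheticTrial-class] whose recording has `nTrials` channels
#'   (`"trials_as_channels"`); its truth is the unjittered template.
#' @export
generateErpSession <- function(nTrials, spec, latencyJitterSd = 0,
                               amplitudeJitterSd = 0,
                               layout = c("channels",
                                          "trials_as_channels")) {
  stopifnot(is(spec, "SyntheticSpec"))
  layout <- match.arg(layout)
  nTrials <- as.integer(nTrials)
  if (nTrials < 1L) stop("'nTrials' must be >= 1")
  if (spec@sharedKind != "erp_bump")
    stop("sessions are defined for 'erp_bump' specs")
  .withSeed(spec@seed, {
    latJit <- stats::rnorm(nTrials, 0, latencyJitterSd)
    ampJit <- 1 + stats::rnorm(nTrials, 0, amplitudeJitterSd)
    lat <- spec@sharedParams$latency + latJit
    if (any(lat < 0 | lat > spec@duration))
      stop("latency jitter pushes the bump outside the epoch")
    trials <- lapply(seq_len(nTrials), function(r) {
      sp <- spec
      sp@sharedParams$latency <- lat[r]
      sp@sharedParams$amplitude <- spec@sharedParams$amplitude * ampJit[r]
      if (layout == "trials_as_channels") {
        sp@nChannels <- 1L
        sp@channelGains <- 1
      }
      .generateTrialImpl(sp)
    })
    if (layout == "channels") return(trials)
    data <- do.call(rbind, lapply(trials, function(tr) tr@recording@data))
    rec <- multiChannelRecording(data, fs = spec@fs,
      channelLabels = sprintf("trial%02d", seq_len(nTrials)))
    T <- ncol(data)
    t <- (0:(T - 1L)) / spec@fs
    truth <- .erpBump(t, spec@sharedParams$latency,
      spec@sharedParams$width, spec@sharedParams$amplitude)
    new("SyntheticTrial", recording = rec, truth = truth,
      truthBand = .truthBandOf(spec))
  })
}

#' @rdname accessors
#' @export
setGeneric("trialRecording", function(x) standardGeneric("trialRecording"))

#' @rdname accessors
#' @export
setGeneric("trialTruth", function(x) standardGeneric("trialTruth"))

#' @rdname accessors
#' @export
setGeneric("truthBand", function(x) standardGeneric("truthBand"))

#' @rdname accessors
#' @export
setMethod("trialRecording", "SyntheticTrial", function(x) x@recording)

#' @rdname accessors
#' @export
setMethod("trialTruth", "SyntheticTrial", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("truthBand", "SyntheticTrial", function(x) x@truthBand)

setMethod("show", "SyntheticTrial", function(object) {
  cat(sprintf("SyntheticTrial: %d channel(s) x %d samples @ %g Hz",
    nrow(object@recording@data), ncol(object@recording@data),
    object@recording@fs))
  if (!is.na(object@truthBand))
    cat(sprintf(", truth in band %d", object@truthBand))
  cat("\n")
})
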