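---
title: "Channel component correlation analysis: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel component correlation analysis: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccca)
```

## The model

A multi-channel EEG recording `X` (channels × samples) is modelled as a
shared, band-limited component appearing on every channel with
channel-specific gain, plus noise that is independent across channels. Under
this model the cross-channel covariance is carried almost entirely by the
frequency band that hosts the shared component, which suggests a two-stage
procedure:

1. decompose every channel into the *same* set of frequency bands, giving
   per-channel band stacks `F_i` (m bands × T samples);
2. find one weight vector `w` over bands maximizing the summed covariance
   between the weighted band mixtures `s_i = wᵀ F_i` of different channels,
   normalized by their total variance:

   $$\max_w \; w^\top S w \quad \text{s.t.}\quad w^\top Q w = 1,
   \qquad S = \sum_{k \ne l} \mathrm{cov}(F_k, F_l),\quad
   Q = \sum_i \mathrm{cov}(F_i, F_i).$$

The stationarity condition `S w = λ Q w` is a generalized eigenproblem. Its
leading eigenvector concentrates weight on the band the channels share; the
remaining columns give successively less-correlated mixtures. The common
component is `y = wᵀ (1/n_c) Σ_i F_i`.

Assumptions worth stating: the shared component occupies (mostly) one of the
detected bands; noise is uncorrelated between channels (instrument and
background cortical noise, not volume-conducted artifacts, which *are*
correlated across electrodes); second-order statistics suffice — unlike ICA,
no non-Gaussianity is required, and unlike PCA, no signal/noise
uncorrelatedness within a channel.

## The empirical wavelet transform

The frequency axis is normalized to `[0, π]` (`w = 2πf/fs`). Given N − 1
boundaries, the bank holds one low-pass scaling filter and N − 1 band-pass
wavelet filters with Meyer-type cosine/sine roll-offs of half-width
`τ_n = μ·w_n` around each boundary, shaped by the auxiliary polynomial

$$\beta(x) = x^4(35 - 84x + 70x^2 - 20x^3).$$

With the coefficient 84 the polynomial satisfies `β(1) = 1` and
`β(x) + β(1−x) = 1`, which is exactly what makes `cos²+sin²` transitions sum
to one; the variant with 85 that sometimes appears in print breaks `β(1) = 1`
and with it the tight-frame property, so this package fixes the coefficient
at the standard Meyer value. Squared responses summing to one at every
frequency gives perfect reconstruction when the same real filter is applied
at analysis (inner product) and synthesis (convolution); in the frequency
domain each band is simply the signal spectrum times the squared response.
Filters are evaluated in closed form on each signal's own FFT grid, so no
resampling error enters; the tabulated grid on the bank object
(`gridSize = 2048` by default) exists for inspection and validity checking.

**Boundary detection.** No single segmentation rule is canonical. The package
smooths the channel-averaged magnitude spectrum with a short moving average
(~2% of the grid), keeps the N largest local maxima, and places each boundary
at the global minimum between consecutive maxima — the classical
inter-peak-minimum rule from the EWT literature. If fewer than N maxima
exist, it falls back to N equal-width bands with a warning. Explicit
boundaries can always be passed instead, which the tests use for exactness.

**Transition parameter μ.** Unspecified in most descriptions beyond "no
overlap". The default is `0.25 · min over consecutive boundaries (including
π) of (w_{n+1} − w_n)/(w_{n+1} + w_n)`, which guarantees disjoint transition
zones for any admissible boundary set; any explicit μ in (0, 0.5) is
validated against the no-overlap condition, naming the offending pair.

**One bank for all channels.** Boundaries are detected once from the
channel-averaged spectrum and the same bank is applied to every channel.
Without this, "band j" would mean different frequency ranges in different
channels and a single weight per band would be meaningless.

**Band ordering.** Components are ordered low → high frequency: band 1 is the
scaling (lowest) band. Descriptions that number decomposition "layers" from
high to low frequency call the three lowest bands of a five-band split
"layers 3–5"; in this package those are `bandIndices = 1:3`, the default for
`ccca()` and the natural choice for event-related potentials, whose energy
sits below ~8 Hz. For steady-state responses pass `bandIndices =
seq_len(nBands)` so the stimulus band is always available.

## Numerical choices

- **Covariance estimator**: sample covariance with mean removal and
  denominator T − 1 throughout; band rows are centered at stacking time.
- **S as a matrix**: the summed-cross-covariance objective is implemented as
  `S[g,h] = Σ_{k≠l} cov(f_{k,g}, f_{l,h})` — the only reading under which
  the scalar objective equals `wᵀSw` identically. S is computed as
  `cov(Σ_k F_k) − Q` and symmetrized to remove floating-point asymmetry.
- **Ridge**: `Q⁻¹S` presumes invertibility that near-degenerate band stacks
  (a nearly empty band) do not provide. When Q's smallest eigenvalue falls
  below `1e-10` of its largest, `1e-8 · trace(Q)/m` is added to the diagonal
  and recorded in the pencil and in the output metadata.
- **Eigensolver**: Cholesky reduction `Q = RᵀR`, symmetric eigendecomposition
  of `R⁻ᵀSR⁻¹`, back-substitution. This keeps eigenvalues real, returns
  columns with `wᵀQw = 1` exactly, and is verified in the tests against
  brute-force Rayleigh-quotient maximization over 10⁵ random Q-normalized
  directions.
- **Sign conventions**: eigenvector columns are flipped so the
  largest-magnitude entry is positive; the extracted `y` is additionally
  aligned to correlate nonnegatively with the channel-averaged raw signal.
  Both conventions are arbitrary but necessary for reproducible downstream
  similarity values.
- **Degenerate eigenvalues**: repeated λ make individual columns arbitrary
  within their eigenspace; the stable LAPACK ordering is kept and the
  subspace treated as non-identifiable. The identical-channel case (all
  λ equal) is covered by analytic tests.
- **Frequency-recognition ties**: exact power ties are broken toward the
  lower candidate frequency.
- **Similarity metric**: Pearson correlation after mean removal — the
  standard waveform-similarity criterion; the extraction sign convention
  makes its sign meaningful.
- **ICA comparator**: no ICA implementation is bundled with base R, so the
  package implements deflationary fixed-point negentropy maximization with
  the log-cosh contrast, seeded initial directions, tolerance `1e-6` and a
  bounded iteration count. ICA gives no rule for which component is "the"
  signal; the package selects the component with maximal |correlation| to a
  reference (or the channel mean). That selection rule is an evaluation
  convenience of this package, not part of ICA.

## The synthetic generator

`syntheticSpec()`/`generateTrial()` produce
`channel_i = gain_i · shared(t) + noise_i(t)` with noise drawn independently
per channel and scaled so the realized shared-to-noise power ratio matches
`snrDb` exactly per channel. Three shared components cover the use cases: a
Gaussian-windowed positive deflection (default latency 0.4 s, width 0.1 s —
a P300-like transient whose spectral energy is ≥ 90% below 8 Hz), a tone plus
harmonics with `1/h` amplitudes and optional per-channel phase jitter
(SSVEP-like), and unit-RMS band-limited Gaussian noise whose default passband
(55–70 Hz at fs = 250) sits strictly inside band 3 of the equal-split
five-band bank — the configuration used for parameter-recovery checks, where
the ground-truth band is known by construction. Background noise is white or
pink; pink is produced by spectral shaping of white noise with `f^{-1/2}`
amplitude, i.e. a `1/f` *power* spectrum, which is what "pink" means as an
EEG background proxy. `generateErpSession()` adds per-trial latency and
amplitude jitter and supports both multi-trial layouts: channels within one
trial, or repeated trials of one electrode stacked as channels.

What the generator deliberately does **not** emulate: volume conduction (a
forward head model would correlate the *noise* across channels),
eye-blink/EMG artifacts, non-stationary background rhythms, and inter-subject
variability. Passing tests therefore demonstrate correctness of the
machinery under the model's assumptions, not performance on arbitrary real
recordings — on real data the assumption most likely to bend is noise
independence across neighboring electrodes.

Default study conditions mirror the intended applications: 8 channels,
250 Hz, 1-s trials at 0 dB SNR for steady-state experiments; 0.8-s epochs,
56-trial sessions for event-related experiments; five bands with the three
lowest retained for ERP analysis.

## Problem sizes in the tests

The test suite and acceptance script run at desk scale by choice: 100 seeded
signals of length 1000 for frame/reconstruction properties, 100 random
pencils (m ≤ 6) with 10⁵-direction Rayleigh searches for the solver, 100
seeded 8-channel trials for band recovery and for end-to-end SSVEP
recognition. These sizes put Monte-Carlo rates well inside their acceptance
margins (e.g. recovery is specified at ≥ 95/100 and achieves 100/100) while
keeping the full suite under half a minute.

## Known limitations

- Only CSV I/O is built in; EDF and other clinical formats need an external
  converter.
- The per-subject accuracy table ships as a packaged fixture for the
  bookkeeping operations; recomputing those absolute accuracies requires the
  external benchmark recordings and is out of scope offline.
- Eigenvector columns inside a repeated-eigenvalue subspace are reported in
  solver order and should not be interpreted individually.
- The boundary detector is intentionally simple (smoothed inter-peak
  minima); spectra with many near-equal peaks may segment differently under
  small perturbations — pass explicit boundaries where stability matters.
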