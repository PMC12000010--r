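# ccca: channel component correlation analysis for multi-channel EEG

Multi-channel EEG recordings are redundant by construction: the neural
component of interest (an event-related potential such as the P300, or a
steady-state visual evoked response) appears on many electrodes at once,
buried in channel-specific background noise. `ccca` extracts that common
component by exploiting exactly this structure — signal correlates across
channels, noise does not — without the assumptions that limit the two
standard tools (PCA assumes signal and noise are uncorrelated; ICA needs an
extra, unsolved step to decide which independent component is the signal).

## The method

For a recording `X = [x_1, …, x_nc]` (channels × samples):

1. **Empirical wavelet transform (EWT).** The channel-averaged magnitude
   spectrum is segmented into `N` bands (boundaries at the minima between the
   `N` largest spectral peaks), and one Meyer-type filter bank is built on
   those boundaries. Squared filter magnitudes sum to one at every frequency
   (a tight frame), so each channel decomposes into band components
   `F_i = [f_{i,1}, …, f_{i,m}]` that sum back to the channel exactly.

2. **Band-weight optimization.** A single weight vector `w` over the bands
   defines per-channel components `s_i(t) = Σ_j w_j f_{i,j}(t)`. The weights
   maximize the summed cross-channel covariance, subject to unit total
   variance:

       max_w  wᵀ S w   s.t.  wᵀ Q w = 1,
       S = Σ_{k≠l} cov(F_k, F_l),   Q = Σ_i cov(F_i, F_i).

   The Lagrangian condition `S w = λ Q w` is a symmetric-definite generalized
   eigenproblem; the leading eigenvector gives the largest weight to the band
   the channels share, the eigenvalue ranks the extracted components.

3. **Extraction.** The common component is `y = wᵀ · (1/n_c) Σ_i F_i`; the
   per-channel components `s_i` are also returned.

The package also provides the PCA and ICA comparators, evaluation tools
(periodogram, SSVEP frequency recognition by spectral argmax, superposition
averaging, Pearson waveform similarity, per-subject best-method bookkeeping),
a seeded synthetic EEG generator (ERP bump, SSVEP tone + harmonics,
band-limited noise; white or pink background), CSV I/O and a CLI.

## Worked example

```r
library(ccca)

spec  <- syntheticSpec(nChannels = 8, fs = 250, duration = 1,
                       sharedKind = "ssvep_tone", snrDb = 0, seed = 3)
trial <- generateTrial(spec)              # 10 Hz tone + harmonics, 0 dB noise
fit   <- ccca(trialRecording(trial), nBands = 5, bandIndices = 1:5)
fit
#> CCCAResult: 8 channel(s), 5 band(s) retained of 5
#>   boundaries (Hz): 10.00, 17.00, 27.00, 38.00
#>   eigenvalues: 5.937, 5.02, 3.491, -0.1731, -0.2394
#>   dominant band (|w1|): 2 of bands {1, 2, 3, 4, 5}

ps <- powerSpectrum(commonComponent(fit), fs = 250, nfft = 1000)
recognizeFrequency(ps, candidates = 8:15)
#> [1] 10
similarity(commonComponent(fit), trialTruth(trial))
#> [1] 0.838
```

The detected boundaries bracket the 10 Hz stimulus and its harmonics; the
leading eigenvalue (5.94, against a theoretical maximum of `n_c - 1 = 7` for
perfectly correlated channels) shows most cross-channel covariance is
captured by one weight set; the component's spectral argmax over the
candidate set recovers the true stimulation frequency.

Bookkeeping on the packaged per-subject SSVEP accuracy table:

```r
tab <- ssvepAccuracyTable()
bestMethodCount(tab)                              # subjects where CCCA is best
#> [1] 12
accuracyDifference(tab, "S26", "ccca", "pca")     # percentage points
#> [1] 45.84
```

## Command line

```sh
Rscript exec/ccca.R simulate --kind ssvep --out sim/ --seed 3
Rscript exec/ccca.R extract  --input sim/recording.csv --fs 250 \
        --n-bands 5 --bands 1,2,3,4,5 --mu auto --out out/ --seed 3
Rscript exec/ccca.R evaluate --mode ssvep --input out/y.csv --fs 250 \
        --candidates 8,9,10,11,12,13,14,15
```

`extract` writes `y.csv`, `s_per_channel.csv`, `weights.csv` and
`metadata.json` (boundaries in Hz, transition parameter, ridge, seed);
identical invocations produce byte-identical files.

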