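---
title: "Measuring neural tracking of self-other synchronization error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring neural tracking of self-other synchronization error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dyadcoh)
```

## The problem

When two people synchronize continuous improvised movements — the "mirror
game" setting, where partners produce original, drifting forearm
oscillations with or without assigned leadership roles — the instantaneous
discrepancy between their positions is a continuously varying visual error
signal. `dyadcoh` quantifies how strongly, and with what latency, each
partner's EEG tracks that error.

The measurement chain is:

1. **Error construction.** Each trial's two motion traces are projected
   onto a single common spatial axis (the first principal axis of the
   *stacked* two-participant positions), and the self-other error is the
   absolute difference of the projections, resampled to the EEG rate.
2. **Coherence.** Magnitude coherence between every EEG channel and the
   error,
   $\mathrm{Coh}(f) = |S_{xy}(f)| \, / \sqrt{S_{xx}(f)\, S_{yy}(f)}$,
   estimated by multitaper cross-spectra on 5 s epochs with 50% overlap,
   3 Slepian tapers, pooled over all epochs and trials of a condition,
   on a 0–10 Hz grid with 0.2 Hz resolution.
3. **Chance baseline.** The same coherence computed after pairing each
   trial's EEG with a *different* trial's error, over all derangements of
   the trials within a condition (9 for 4 trials), averaged into one
   baseline spectrum. This preserves both signals' spectra while
   destroying genuine alignment.
4. **Lag scan.** Band-averaged (0–6 Hz) coherence recomputed with the
   error shifted over a −2…+2 s grid in 0.02 s steps (201 lags); the peak
   of the profile estimates the tracking latency. Positive peak lag means
   brain activity lags the error.
5. **Movement control.** The same lag scan between the error and the
   absolute rate of change of a partner's instantaneous movement
   frequency (Hilbert phase derivative), which indexes overt movement
   adjustments rather than neural tracking.
6. **Statistics.** Point-wise paired *t* tests (or Pearson correlations)
   along the frequency axis, corrected by cluster-based permutation:
   contiguous supra-threshold frequencies form clusters scored by the sum
   of |*t*|, compared against the permutation distribution of the maximum
   cluster mass under sign flips (or subject shuffles for correlations).

## Assumptions

* Tracking is modelled as *linear*: coherence detects consistent phase
  and amplitude coupling per frequency. Nonlinear locking (e.g.
  frequency-doubled responses) is invisible to it.
* Pooling cross-spectra across epochs and trials before forming coherence
  assumes stationarity of the coupling within a condition.
* The lag scan interprets time shifts, so all conditioning filters are
  zero-phase, and lags are exact integer sample shifts (no
  interpolation).
* Cluster adjacency is one-dimensional along frequency, which matches
  channel-averaged (or group-averaged) spectra; no channel neighbourhood
  structure is used.

## The synthetic dyad generator

Real recordings of this task (motion capture at 240 Hz, 64-channel EEG at
2048 Hz downsampled to 500 Hz, 180 s trials, 4 per condition) are not
bundled; the generator produces data with the statistical structure the
analysis assumes, plus exact ground truth:

* **Movement**: two phase oscillators around `base_freq` (default 1 Hz, the
  comfortable forearm-oscillation rate). Partner A's instantaneous
  frequency performs a reflected random walk (`drift_std`, Hz·s^-1/2 —
  "improvisation"); the adapting partner's phase is attracted to the
  other's phase delayed by `follower_delay_s` with gain
  `coupling_strength × 2π` rad/s. `follower`: B adapts to A; `leader`:
  roles swap; `joint`: both adapt at half gain. Amplitude is modulated by
  an independent slow random walk, and positions are embedded in two
  spatial axes with a fixed 0.15 rad tilt, a 5% elliptical minor
  component, and 1% white positional noise — enough structure to make the
  principal-axis projection meaningful.
* **EEG**: `n_tracking_channels` carry the demeaned error shifted by
  `tracking_lag_s` (positive = EEG lags error), scaled so tracking power
  over 1/f background power equals `tracking_snr`; remaining channels are
  background only. `tracking_band_hz` optionally low-passes the embedded
  image, modelling tracking confined to a band (set to 6 Hz in the
  structure checks); the default `Inf` keeps the noiseless limit exactly
  equal to the shifted error.
* **Determinism**: every stochastic component draws from a substream
  derived from one integer seed (`derive_seed()`), so identical
  configurations reproduce trials bit-identically.

What the generator does **not** emulate: biomechanics, blinks and ocular
artifacts, volume conduction and channel covariance, nonstationary
coupling, or behavioural realism of improvisation beyond spectral
plausibility. Tests passing on this generator therefore validate the
*estimators* (calibration, recovery, error control), not claims about
real EEG.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `epoch_len_s` | 5 s | sets the 0.2 Hz frequency resolution needed below 1 Hz |
| `overlap` | 0.5 | halves estimator variance at negligible cost |
| `n_tapers` | 3 | Slepian tapers; realized smoothing half-bandwidth `(k+1)/(2T)` = 0.4 Hz |
| `f_max` | 10 Hz | movement-error content lives far below this |
| `band` | 0–6 Hz | the band where tracking exceeds chance at the sensor level; inclusive of the 6.0 Hz bin |
| lag grid | ±2 s, 0.02 s | 201 lags; each step is an exact sample shift at 500 Hz |
| `n_perm` | 1000 | sign-flip permutations; p-values use the add-one convention |
| `alpha` | 0.05 | two-sided parametric cluster-forming threshold |

With 5 s epochs a ±0.3 Hz multitaper half-bandwidth would admit only
2 Slepian tapers (2TW − 1); the estimator fixes 3 tapers and *reports*
the realized half-bandwidth 0.4 Hz rather than guessing unstated padding.
A single Hann taper is available via `taper = "hanning"`.

## Numerical choices

* **Resampling** (error 240→500 Hz; EEG decimation) is Fourier-domain
  band-limited resampling: amplitude-exact in band, brick-wall
  anti-aliasing. Polyphase FIR resampling was tried first and rejected:
  its passband ripple (~10^-4) and edge transients exceeded the
  tolerances the closed-form checks demand. The periodic-extension
  transient at the ends is absorbed by epoching.
* **Filtering** is zero-phase throughout (`filtfilt`); the 0.1 Hz
  high-pass is two cascaded second-order Butterworth stages (numerically
  robust at very low normalized cutoffs), notches are second-order
  band-stops at 50 Hz and harmonics below Nyquist, and channels are
  demeaned before filtering so a DC offset excites no onset transient.
* **Instantaneous frequency** uses the FFT analytic signal, unwrapped
  phase, and Savitzky–Golay derivatives (0.5 s window, order 3): a plain
  finite difference multiplies the sample-scale Hilbert-phase ripple by
  the sampling rate and buries the slow frequency adjustments of
  interest. The discrete analytic signal also carries a ripple at twice
  the oscillation frequency, so the instantaneous frequency is low-passed
  (zero-phase FFT brick wall after linear detrending, `smooth_hz` =
  0.5 Hz) before the second derivative; frequency *adjustments* in this
  task are much slower than the ~1 Hz movement itself.
* **DPSS tapers** come from the symmetric tridiagonal formulation; for
  epochs longer than 512 samples they are computed on a 512-point grid,
  spline-interpolated, and re-orthonormalized (classical shortcut; the
  concentration loss is negligible at these bandwidths).
* **Undefined coherence** (zero auto-power) propagates as `NA`, never 0,
  and is excluded from band averages; a constant control signal yields an
  all-`NA` profile rather than a spurious null.
* **Peak ties** break toward the smallest |lag|, then negative before
  positive (a tie should not manufacture a latency claim).
* **Permutation p-values** are `(b+1)/(m+1)` (never exactly zero; the raw
  proportion is available), with a 10^-8 relative tolerance when
  comparing observed cluster mass to null maxima so exact ties survive
  differing arithmetic paths. Permutations with no supra-threshold
  cluster contribute a maximum mass of zero.
* **Unequal trial lengths** in surrogate pairings are truncated to the
  shorter member's whole-epoch count.

## Design choices that were genuinely open

* **Joint vs per-participant PCA**: the axis is fitted on the stacked
  two-participant data, because a difference of projections onto two
  different axes is not a spatial error; `joint = FALSE` exposes the
  per-participant variant.
* **Pooled CSD vs averaged per-trial coherence**: condition-level
  coherence is the coherence of the pooled cross-spectral density — the
  stabler estimator and the standard reading of condition-level
  coherence.
* **Derangements, not all permutations**: identity pairings would leak
  genuine coherence into the chance baseline; the 9 fixed-point-free
  pairings of 4 trials are enumerated exhaustively, in lexicographic
  order.
* **Lag sign convention**: at lag τ the EEG at time *t* is compared with
  the error at *t − τ*, so a positive peak lag means brain modulations
  lag the error. The convention is pinned by a constructed-shift test.
* **Correlation permutations** shuffle subject labels of one variable;
  sign flips are undefined for correlations.
* **Region-style averaging** operates on named channel groups (profiles
  averaged, then the peak extracted from the averaged profile); source
  imaging is out of scope, so channel groups stand in for anatomical
  regions on synthetic data.
* The command-line surface is the R API plus `scripts/acceptance.R`; an
  end-to-end run is one `run_pipeline()` call on a `run_config()`, which
  echoes its configuration and writes a manifest with per-file checksums
  so every number is traceable to a config and seed.

## Problem sizes used in the checks

The packaged tests and the acceptance script run the full chain at
reduced problem sizes, chosen once: 20–60 s trials at 100 Hz with 1–3
channels for recovery and calibration suites; 200 simulated participants
for surrogate validity; 500 null datasets of 56 subjects × 51 frequencies
(200 sign-flip permutations) for family-wise error; 12 participants ×
2 conditions × 4 trials for the leadership-structure checks. The
generator's *defaults* remain the nominal study conditions (180 s trials,
240 Hz motion, 500 Hz EEG, 4 trials per condition).

## Known limitations

* Sensor-space only: no head model, no source reconstruction; channel
  groups are a stand-in for anatomical regions.
* The coherence-to-error-power ratio divides by estimated error power and
  is unstable where that power is near zero; it is reported band-averaged.
* The multitaper half-bandwidth (0.4 Hz) smears sharp band edges by about
  one frequency bin; a 6 Hz-limited signal shows coherence up to ~6.4 Hz.
* The surrogate baseline assumes trials within a condition are
  exchangeable; slow session drifts would violate this.
* At the smallest permitted sample sizes (n = 3 paired subjects) the
  cluster-forming threshold is large and power is minimal; the test is
  valid but uninformative there.
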