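---
title: "Individualized SO-spindle coupling: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized SO-spindle coupling: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sospindle)
```

## The scientific problem

During non-REM sleep the cortex generates slow oscillations (SOs, < 2 Hz:
a deep negative "down-state" trough followed by a positive "up-state"
peak) and the thalamus generates sleep spindles (transient 10-17 Hz
bursts, 0.5-3 s). The systems-consolidation account of sleep-dependent
memory holds that information transfer is most effective when spindles
ride the depolarizing SO up-state, so the *consistency* of the SO phase
at which spindles occur - not the abundance of either event - is the
quantity of interest. `sospindle` implements an individualized pipeline
for estimating that consistency from multichannel scalp EEG, together
with a behavioral learning-curve parameterization and the nonparametric
cluster statistics needed to relate the two across a cohort, and a
synthetic-data generator that makes every stage testable by parameter
recovery.

The pipeline has five analysis stages:

1. **Spectra and IRASA** (`compute_spectra()`): sliding 15-s Hanning
   windows over continuous runs of the requested sleep stages give the
   total power spectrum; irregular-resampling auto-spectral analysis
   separates the fractal (1/f) component, and the residual
   (total - fractal) exposes each subject's oscillatory peaks.
2. **Individualized event detection** (`find_peaks()`,
   `detect_spindles()`, `detect_slow_oscillations()`): the spindle
   detector is centered on each channel's own residual peak frequency
   (+/-2 Hz); both detectors use relative (percentile) amplitude
   criteria, so they are invariant to channel gain.
3. **Coupling** (`znorm_epochs()`, `gate_cooccurrence()`,
   `subject_coupling()`): spindle epochs are z-normalized, restricted to
   those with a slow oscillation within 2.5 s on the same channel
   (default stage N3 only), and the SO phase at each spindle peak is
   read out; the mean resultant length R of those phases is the coupling
   strength (1 - circular variance), the circular mean the preferred
   phase.
4. **Behavior** (`fit_learning_curve()`, `overnight_change()`): cascade
   counts per 3-min block are fit with a least-squares line per
   performance test; the slope m is the learning curve and y1 = m + c
   the task proficiency (the model's value at block 1); overnight change
   is post minus pre.
5. **Statistics** (`cluster_permutation_test()`,
   `cluster_corrected_spearman()`, `partial_spearman()`): family-wise
   error over the sparse 11-channel montage is controlled with
   cluster-based permutation (max-size criterion); correlations use
   Spearman rank statistics with the rho-to-t transform for
   thresholding.

## Conventions that must agree across modules

Two conventions are defined once and shared between the generator and the
analysis, because any mismatch would masquerade as a coupling effect:

* **Phase convention**: the SO component is the < 2 Hz zero-phase-filtered
  signal; its analytic-signal phase is 0 at the up-state peak and +/-pi at
  the trough (cosine convention). `rvonmises()` draws and
  `so_phase_at_spindle_peak()` readouts both use it.
* **Time convention**: all times are seconds from recording start; sample
  1 is t = 0; epochs are +/-2.5 s around the event center (spindle
  positive peak; SO filtered-signal trough).

## The synthetic generator and what it emulates

`generate_recording()` builds each channel as 1/f^alpha Gaussian noise
plus planted events; `generate_cohort()` wraps per-subject
configurations and a block-level behavior table.

* **Fractal background**: spectral exponent `fractal_slope = 2` and SD
  `fractal_offset = 15` uV. Deep-sleep scalp EEG shows steep 1/f slopes
  (roughly 2-3 below 20 Hz); the spectrum plateaus below 0.3 Hz because
  real recordings are high-pass limited - an unbounded 1/f^2 would place
  essentially all variance below 0.01 Hz and leave the spindle band
  unrealistically silent.
* **Slow oscillations**: two-cycle sinusoidal trains at `so_freq = 0.75`
  Hz, 75 uV half-wave amplitude, 4 troughs per eligible minute, with
  raised-cosine ends. Trains, not lone cycles, are what stage-N3 EEG
  shows; the waveform ends are smoothed because a derivative
  discontinuity injects broadband transients that the spindle band-pass
  would detect as SO-locked pseudo-spindles, and an isolated cycle's
  boundary zero-crossings would be unpinned against noise.
* **Spindles**: sinusoids at the subject's spindle frequency (drawn from
  11-15 Hz per subject) under a Gaussian envelope (sigma = duration/6),
  1 s, 20 uV peak, 2 per eligible minute. A configurable fraction
  (default 0.8) is planted on an SO at a phase drawn from von
  Mises(mu, kappa); the rest are placed at least 3 s from any SO trough
  as negative controls for the co-occurrence gate.
* **Behavior**: each subject has a latent baseline proficiency, learning
  rate, and an overnight proficiency gain built by blending noise with
  the normal scores of the kappa ranks; the blend weight is calibrated
  so the *sample* Spearman correlation between kappa and gain lands on
  the configured `target_rho` (at n = 20 an uncalibrated population-level
  construction would wander by +/-0.18 across cohort draws and dominate
  every downstream power property). The test-2
  proficiency exceeds test 1 by exactly the gain, and the slope flattens
  by half the gain, reproducing the trade-off between overnight
  improvement and subsequent learning curve. Block scores are the latent
  line plus Gaussian noise (SD 1.5 cascades), truncated at zero and
  rounded, since cascade counts are non-negative integers.

Default SO/spindle densities are configuration knobs chosen as
mid-range values for stage N3, not claims about any particular cohort.

What the generator deliberately does **not** emulate: sleep
microarchitecture (arousals, stage transitions within an epoch, REM
phenomena), ocular/muscle artifacts, volume conduction (channels share
event times but carry independent noise), amplitude asymmetries between
channels, and non-Gaussian background dynamics. Passing recovery tests
on this generator therefore demonstrates the correctness of the
estimators under their own assumptions - not robustness to artifacts,
which on real data requires the usual upstream cleaning.

## Numerical choices

* **IRASA**: resampling factors 1.10-1.90 in 0.05 steps. Resampling is
  done in the Fourier domain (spectrum truncation/zero-padding), which
  is exact for band-limited content and lets all channels be resampled
  with one matrix FFT; spectra are averaged across windows per factor
  and direction *first*, and the geometric pair mean and the median
  across factors are taken on those low-variance estimates. Taking the
  median per window instead would bias the fractal component low by the
  chi-square sampling noise of raw periodograms (the geometric mean of
  two independent exponentials has expectation 0.785 of their mean).
* **Windows**: 15-s segments stepping 1 s by default, never crossing a
  stage-run boundary; all windows weighted equally. The step is a
  parameter (`step_s`); large simulations in the test-suite and the
  acceptance script use 5-20 s steps, which changes only the variance of
  the spectral estimates, not their expectation.
* **Filters**: zero-phase (forward-backward) Butterworth, order 3 per
  pass, for the spindle band-pass, the SO 0.16 Hz high-pass + 2 Hz
  low-pass cascade, and the epoch-level 2 Hz low-pass (the latter with
  reflection padding, since a +/-2.5 s epoch is short against a 1.3-s SO
  period). Zero-phase filtering preserves event timing, on which the
  phase readout depends.
* **Percentiles**: linear interpolation between order statistics
  (quantile type 7); amplitude comparisons use `>=`, so candidates tied
  with the threshold are kept - with 100 identical candidates, all pass.
* **Cluster statistics**: element-wise t (pooled variance, or paired),
  two-sided threshold at `cluster_alpha`, signed clusters by montage
  adjacency, max-size criterion against the permutation null of the
  maximum over both signs, Monte-Carlo p with the (b+1)/(n+1)
  correction. Subject rows are canonicalized (sorted) before the
  permutation loop, making results exactly invariant to input order at
  a fixed seed. |rho| = 1 maps to a capped t value rather than Inf.
* **TFR baseline z**: the bootstrap distribution pools the power of
  every trial at every baseline bin (-2 to -1.5 s), so the z scale is
  commensurate with single-trial, single-bin variability; a
  trial-averaged statistic would make the z magnitude depend only on
  the trial count and drift from zero on stationary data.
* **Minimum events**: channel-level coupling strength is reported only
  for >= 10 gated events (configurable), because the mean resultant
  length is strongly upward-biased in tiny samples; channels below the
  floor are reported missing, not zero.

## Detector behavior on noisy data - what to expect

The amplitude criteria are *relative*: the spindle threshold is the 75th
percentile of the smoothed Hilbert envelope over stage-eligible samples,
the SO threshold the 75th percentile of candidate trough-to-peak
amplitudes. Two structural consequences follow, and they are properties
of this detector family, not implementation artifacts:

* On band-limited Gaussian background *alone*, roughly a quarter of
  samples exceed the spindle threshold, and excursions of 0.5-3 s occur
  at about 4-5 per minute regardless of the noise amplitude (the
  threshold is scale-invariant). Detected spindle sets therefore always
  contain threshold-crossing background events alongside planted ones;
  at two planted spindles per minute, precision against planted ground
  truth is ~0.35 while recall is ~1.
* The SO criterion keeps the top quarter of candidates, so precision is
  capped at plant_rate / (0.25 x candidate_rate); at the default
  densities this is ~0.66, with recall ~0.9.

Because background events carry no consistent SO phase, their effect on
the coupling strength is a roughly constant multiplicative dilution of
R: recovered preferred phases are unbiased (planted mu is recovered
within ~0.1 rad through the full chain), kappa ranks are preserved, and
group or correlation analyses on R are unaffected in direction. Users
comparing absolute R values across pipelines with different event
selections should expect level differences for this reason.

## Problem sizes used in validation

The test-suite and `scripts/acceptance.R` validate with: 10-20 min
single-channel recordings for spectral and detector checks (sampling
rate 128 Hz, ample for a 17 Hz spindle ceiling); a 20-subject cohort
with ~60 min of N3 per subject and 20-s spectral steps for the
end-to-end recovery; 200 null repetitions at 200 permutations for the
calibration of both cluster tests; and 500-sample phase sets for the
circular-statistics recovery. These sizes are the package's choices for
stable Monte-Carlo estimates; all of them are parameters of the
corresponding functions.

## Statistical power of the cohort-level cluster correlation

With 20 subjects, a kappa-gain rank correlation of 0.6, block-score
noise of 1.5 cascades, and the cluster correction at alpha 0.05, the
per-channel coupling-vs-proficiency-change correlation sits near 0.45-
0.50 - right at the two-sided significance threshold for n = 20
(|rho| = 0.44). A surrogate simulation (EEG stage replaced by its
measured fidelity, 100 cohort draws) puts the probability of a
significant central-channel cluster at roughly 0.4-0.55 per cohort.
Detecting this effect size reliably needs either more subjects (the
power construction reaches ~80% flags at n = 40) or a stronger
underlying association; single-cohort cluster outcomes at n = 20 should
be read accordingly.

## Known limitations

* Phase readout assumes the spindle peak sits at the epoch center; if
  epochs are built by other means the readout time must be adjusted.
* The co-occurrence gate takes the nearest same-channel SO; it does not
  model multi-SO competition or cross-channel gating.
* The percentile-threshold detectors are not artifact-aware; on real
  recordings, stage masking is the only rejection applied here and
  upstream artifact handling is the user's responsibility.
* The cluster permutation test assumes exchangeability across subjects
  under the null (group labels or condition signs); it is not designed
  for within-subject time-series dependence beyond the paired design.
* EEG interchange uses raw float64 binary plus a JSON header
  (`write_recording()`); EDF export is out of scope here, and EDF's
  16-bit quantization would in any case not round-trip the synthetic
  float signals.
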