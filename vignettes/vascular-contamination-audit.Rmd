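---
title: "Auditing vascular contamination of fMRI contrasts with lagged end-tidal CO2 mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing vascular contamination of fMRI contrasts with lagged end-tidal CO2 mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petco2lag)
```

## The problem

Apparent diffusion coefficient fMRI (ADC-fMRI) computes a per-timepoint ADC
from pairs of interleaved diffusion-weighted volumes,

$$\mathrm{ADC}(t) = -\frac{1}{b_2 - b_1}
  \ln\frac{S(b_2, t + \delta t)}{S(b_1, t)},$$

with the intent of tracking neuromorphological (microstructural) dynamics
rather than the blood-oxygenation (BOLD) signal. Because each
diffusion-weighted signal is $S(b,t) = S_0\,e^{-TE/T_2(t)}\,e^{-b\,
\mathrm{ADC}(t)}$, any haemodynamic modulation that enters through $T_2(t)$
multiplies both members of a pair and cancels in the ratio; using
$b \geq 200\ \mathrm{s\,mm^{-2}}$ additionally suppresses intravascular
(IVIM pseudo-diffusion) signal. Whether the residual ADC timeseries is in
fact free of vascular contamination is an empirical question. CO2 is a potent
vasodilator, so respiration — monitored as end-tidal CO2 partial pressure
(pETCO2), sampled once per exhale — provides a vascular driver that is
independent of neural morphology. This package implements the full audit: it
correlates each fMRI contrast (BOLD, the raw b200 and b1000 diffusion
series, and the two-point ADC series) against a lagged pETCO2 regressor,
voxel by voxel, under a cued breath-hold paradigm (strong hypercapnic
stimulus) and in resting breathing (spontaneous fluctuations, pETCO2 power
below 0.05 Hz).

Every stage runs on a synthetic-data generator with known ground truth, so
each claim in the pipeline is testable without any acquisition.

## Pipeline

1. **physio** — the raw expired-CO2 trace is low-pass filtered (1 Hz,
   4th-order Butterworth, zero-phase), end-tidal peaks are detected and
   screened, the peak envelope is linearly interpolated and resampled at
   50 Hz, detrended with a cubic polynomial, and convolved with the canonical
   double-gamma haemodynamic response function (HRF). The result is the
   pETCO2 regressor.
2. **contrast** — interleaved diffusion runs (two b = 0 volumes, then
   alternating b200/b1000) are split into the two b-value series and combined
   into the ADC series via the two-point formula, one ADC sample per pair at
   the pair-midpoint time (effective sampling interval twice the TR).
3. **conditioning** — 4 mm FWHM Gaussian smoothing, 0.01 Hz high-pass
   (4th-order Butterworth, zero-phase), motion QC (reject if maximum absolute
   displacement exceeds one voxel or mean framewise displacement exceeds
   0.2 mm), plus the noise-amplification control and SNR metrics.
4. **lagmap** — per voxel, Pearson correlation between the fMRI series and the
   regressor shifted by lags $-30$ to $0$ s in $0.5$ s steps;
   $r_{max}$, its lag (the latency), and
   $z_{max} = \tanh^{-1}(r_{max})\sqrt{N-3}$ with $N$ the overlap at the peak
   lag. Latencies are normalized to the grey-matter median.
5. **surrogate** — phase-randomized copies of each subject's regressor are
   correlated against voxels drawn from the other subjects (leave-one-out),
   the pooled $z_{max}$ samples forming an empirical null; the one-tailed
   95th percentile is the contrast-specific significance threshold.
   Breath-hold runs use the fixed threshold $z = 3.09$ ($p = 0.001$) instead,
   because every subject's breath-hold regressor is dominated by the task
   frequency and surrogates would retain that periodicity.
6. **stats** — percent significant voxels, mean variance explained
   ($r_{max}^2$), run averaging, Fisher-z map similarity (intra-subject,
   inter-subject, cross-condition), and two-tailed unpaired Mann-Whitney U
   tests with Bonferroni correction across contrast pairs.

## What the synthetic generator emulates

The generator is the package's study definition, not a fixture. Defaults:

* **Breath-hold paradigm**: 4 epochs of 18 s baseline + 14 s hold + 16 s
  recovery (48 s epochs, 192 s runs); resting runs last 880 s.
* **CO2 recording**: raised-cosine breath cycles (5 s period, 12 breaths/min)
  rising to an end-tidal peak and falling to an inspiratory trough near
  2 mmHg; baseline end-tidal 40 mmHg. The cosine cycle has a single spectral
  line at 0.2 Hz, so the 1 Hz detection low-pass leaves peak values intact —
  which is what makes the end-to-end envelope-recovery test exact. During
  holds no exhalation occurs; breathing restarts at the hold end (the cued
  post-hold exhale) and the first post-hold peak carries the full hold
  response (default 8 mmHg, decaying with an 8 s time constant; the
  literature does not pin the magnitude, so it is a free parameter). Resting
  end-tidal values follow a sum of 12 sinusoids between 0.004 and 0.045 Hz
  with 2 mmHg SD, keeping the envelope power below 0.05 Hz by construction.
  The recording starts 20 s before the trigger, ends 30 s after the run, and
  is delayed by a 15 s gas-analyser transport delay, so true fMRI-regressor
  lags sit near $-15$ s — inside the tested range.
* **Vascular coupling**: the driver is the detrended true envelope convolved
  with the unit-sum HRF. BOLD voxels get
  $S = S_0 e^{-TE/T_2}(1 + a_v \, d(t - \ell_v))$ with grey-matter gain
  $a = 0.004$/mmHg (about 0.4%/mmHg, a typical 3 T cerebrovascular
  reactivity), white matter half that, and latencies 1.0 s (GM) and 3.5 s
  (WM) — the 2.5 s separation matching reported GM/WM transit differences.
  Diffusion runs share the same $T_2$ modulation at 70% of the BOLD gain
  (spin echo is less sensitive to susceptibility than gradient echo), plus a
  static IVIM compartment (volume fraction 0.01, $D^* = 10^{-2}$ mm²/s) and
  optionally a neural ADC response; by default the neural response is zero,
  because the audit concerns vascular contamination. Signal constants:
  $S_0 = 2000$, $TE = 105$ ms, $T_2 = 80$ ms, baseline ADC
  $0.8 \times 10^{-3}$ mm²/s, additive Gaussian noise SD 10 (image SNR about
  54 at b = 0; Rician bias is ignored, as these SNRs keep the Gaussian
  approximation accurate and the oracles analytic).
* **Timing conventions**: volume times are acquisition mid-times
  $(i - 0.5)\,TR$; the diffusion T2 modulation is sampled once per
  interleaved pair at the pair midpoint. The vascular driver is band-limited
  below 0.05 Hz, so neglecting its within-pair variation (at most ~0.3 s) is
  harmless, and it makes the two-point ADC *exactly* free of shared T2
  modulation — turning the suppression mechanism into a machine-precision
  test rather than an approximate one.
* **Cohort**: 8 subjects on a 20 x 20 x 10 grid (GM the first half of the x
  axis, WM the rest), 192 breath-hold volumes at TR 1 s (the diffusion run
  has 2 b0 + 190 alternating volumes), resting runs at TR 1.1 s.

What it does **not** emulate: k-space/EPI artefacts, motion-corrupted
resampling, multi-echo combination, Rician noise, registration error,
physiological noise other than the CO2 coupling, and spatially smooth
latency/gain gradients within a tissue. Passing tests therefore demonstrate
the correctness and calibration of the *analysis*, not the fidelity of any
scanner. The denoised/residual split that NORDIC provides on real data is
supplied by the generator's ground-truth split.

## Numerical and design choices

* **Zero-phase filtering** everywhere a Butterworth is specified: a causal
  filter would add a frequency-dependent delay of the order of seconds —
  intolerable in a latency-measurement pipeline. Series are mean-centred and
  odd-reflection padded before the forward-backward pass, so constants pass
  low-pass filters exactly and edge transients stay out of short runs.
* **End-tidal peak screening**: the published procedure reviewed peaks
  manually to remove partial exhales. The reproducible replacement rejects
  peaks falling more than 3 robust SDs *below* a 7-peak moving median of
  peak heights, with the robust scale floored at 5% of the median height
  (breath-to-breath end-tidal variability is under ~10%, partial exhales
  read ~50% low). Rejection is one-sided by default: elevated post-hold
  peaks are physiology, not artefact. A `two_sided` flag restores symmetric
  rejection.
* **HRF**: $h(t) = (t/6)^6 e^{-(t-6)} - \tfrac{1}{6}(t/16)^{16} e^{-(t-16)}$,
  32 s support, peaking at 6 s with a late undershoot; peak-normalized for
  the regressor (normalization is inert for correlation), unit-sum for the
  generator driver (unit gain keeps mmHg units).
* **Envelope extrapolation**: constant hold beyond the first/last peak — no
  fabricated trends at run edges.
* **Lag sign**: $r(\ell)$ correlates fMRI$(t)$ with regressor$(t - \ell)$;
  negative lags mean the fMRI signal leads the *recorded* trace, which is
  how a 15 s transport delay appears.
* **Tie-breaking**: equal-maximum lags resolve toward the range midpoint
  ($-15$ s), minimizing boundary bias; implemented as an infinitesimal
  penalty on distance from the midpoint.
* **$N$ per voxel** is the overlap count at the peak lag (overlap varies by
  lag when the recording margins are short); a `fixed_n` flag uses the run
  length instead.
* **Invalid ADC ratios** ($S \le 0$, possible at very low SNR) are flagged
  per voxel-timepoint and excluded, never clipped.
* **Null consistency**: surrogate pairs whose peak falls at a lag-range
  extreme are excluded from the null, mirroring the boundary-exclusion rule
  of the voxelwise maps. Without this the null is stochastically lighter
  than the statistic it calibrates and the realized false-positive rate runs
  ~1 percentage point high.
* **Residual permutation** in the noise-amplification control permutes whole
  volumes (one permutation shared by all voxels), preserving the spatial
  noise covariance; a `per_voxel` flag gives independent permutations.
* **Quantiles** are empirical order statistics with linear interpolation
  (R type 7).
* **Bonferroni family**: all contrast pairs within a metric (6 pairs for 4
  contrasts), overridable via `n_comparisons`.
* **CSF partial-volume estimator**: compartment diffusivities default to
  CSF $3.0\times10^{-3}$, GM $0.8\times10^{-3}$, WM $0.75\times10^{-3}$
  mm²/s. Whether the perturbation is absolute fraction points or relative to
  the CSF fraction is exposed as a flag (`relative`), since the published
  figure does not disambiguate; the sweep mode reports the extremum over a
  CSF-fraction grid.

## Interpreting latencies

Two properties of lagged-correlation latency mapping matter when reading the
outputs. First, the per-voxel correlation profile $r(\ell)$ is nearly flat
within a few seconds of its maximum (the regressor's autocorrelation is
broad), so single-voxel peak lags jitter by 1-2 s at realistic
contrast-to-noise even though run-level medians are stable; the package's
recovery tests therefore assert the tissue-median latency (within the 0.5 s
grid), not per-voxel accuracy. Second, during a breath hold the end-tidal
envelope is unobservable (no exhalation for 14 s), and the linear
interpolation across the hold starts the modelled rise at the last pre-hold
exhale — several seconds before arterial CO2 actually rises. Absolute
breath-hold latencies are therefore biased toward zero by roughly half the
hold duration. This cancels in everything the analysis reports, because maps
are normalized to the grey-matter median; the GM/WM separation and all
summary statistics are unaffected.

## Problem sizes used in tests and the acceptance analysis

The shipped analyses run the default 8-subject cohort on a 20 x 20 x 10 grid
(4,000 voxels; about 1.5 million voxel-lag correlations per run set), the
resting ADC surrogate null at 100 surrogates x 100 voxels per donor pair
(5,600 pooled pairs), and the calibration experiment at 500 x 500 with 6
subjects (15,000 pooled pairs, ~24,000 fresh null voxels). These sizes give
binomial/quantile standard errors of a few thousandths on the calibrated
false-positive rate — comfortably inside the +/-0.01 assertion — while a
full run of tests plus the acceptance analysis completes in minutes.

## Known limitations

* Group operations assume a shared voxel grid (the synthetic cohort provides
  one); there is no registration or MNI-space machinery.
* The surrogate null treats the regressor as circularly stationary (standard
  phase randomization); regressors with strong non-stationarity inherit a
  per-regressor spread in the conditional false-positive rate, which the
  leave-one-out pooling averages over.
* The automatic peak-review rule replaces human judgement with a fixed
  robust statistic; traces with pathological breathing patterns should still
  be inspected.
* Motion only enters through the QC gate — the generator never resamples
  images, so motion-correction interpolation artefacts are out of scope, as
  are NORDIC, Gibbs unringing, distortion correction and multi-echo
  combination (external preprocessing on real data).
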