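# petco2lag

Audits vascular (CO2-driven) contamination of fMRI contrasts by lagged
end-tidal CO2 correlation mapping — for researchers evaluating apparent
diffusion coefficient fMRI (ADC-fMRI) and diffusion-weighted fMRI (dfMRI) as
non-vascular functional contrasts.

## The question and the method

Respiration changes arterial CO2, a potent vasodilator, and thereby drives
cerebral blood flow with a regionally varying delay. That makes the end-tidal
CO2 pressure (pETCO2, the CO2 level at the end of each exhale) a vascular
reference signal that is independent of neural microstructure. A contrast
that tracks pETCO2 is vascularly contaminated; one that does not is a
candidate readout of neuromorphological dynamics.

ADC-fMRI computes a per-timepoint apparent diffusion coefficient from pairs
of interleaved diffusion-weighted volumes,

    ADC(t) = -1/(b2 - b1) * ln[ S(b2, t + dt) / S(b1, t) ],

where S(b,t) = S0 exp(-TE/T2(t)) exp(-b ADC(t)). Any haemodynamic modulation
entering through T2(t) multiplies both members of a pair and cancels in the
ratio; b-values of at least 200 s/mm² suppress the intravascular (IVIM)
compartment. The package quantifies what survives:

* **physio** — raw expired-CO2 trace → 1 Hz low-pass → end-tidal peak
  detection with automatic outlier screening → 50 Hz linear envelope →
  cubic detrend → double-gamma HRF convolution → the pETCO2 regressor.
* **contrast** — split interleaved b200/b1000 runs, build the two-point ADC
  series, and estimate the CSF partial-volume ceiling on apparent ADC
  responses (three-compartment mixture model).
* **conditioning** — 4 mm FWHM smoothing, 0.01 Hz high-pass, motion QC
  (one-voxel / 0.2 mm mean-FD rules), noise amplification by permuted
  residual injection, image SNR and temporal SNR.
* **lagmap** — voxelwise Pearson correlation at lags -30..0 s (0.5 s steps),
  peak correlation r_max, latency, Fisher z_max = atanh(r_max)·sqrt(N-3),
  grey-matter latency normalization, mean correlation profiles.
* **surrogate** — phase-randomized regressor copies correlated against other
  subjects' voxels (leave-one-out), pooled into an empirical z_max null;
  its 95th percentile is the contrast-specific significance threshold.
  Breath-hold maps use the fixed z = 3.09 (p = 0.001).
* **stats** — percent significant voxels, mean variance explained, map
  similarity (intra-/inter-subject, cross-condition), Mann-Whitney U tests
  with Bonferroni correction.
* **synthetic_data** — a generator for CO2 traces (breath-hold and resting),
  motion, and multi-contrast 4D runs with known coupling gains, latencies,
  IVIM fraction and noise, so every stage is tested against ground truth.

## Worked example

A noiseless diffusion run whose T2 is modulated by the vascular driver, with
no neural ADC change:

```r
library(petco2lag)

trace  <- generate_co2_trace(resting_spec(220), seed = 11)
masks  <- make_masks(c(8, 8, 4))
truth  <- make_ground_truth(c(8, 8, 4), masks$GM, masks$WM,
                            noise_sigma = 0, ivim_fraction = 0)
run    <- generate_fmri_run("dfmri", truth, make_vascular_driver(trace),
                            TR_s = 1.1, n_pairs = 99, seed = 12)
reg    <- process_co2(trace)

sp  <- split_dfmri(run)
adc <- compute_adc_series(run)
range(abs(xcorr_map(sp$b200, reg)$rmax))
#> [1] 0.9986 0.9986
max(apply(t(matrix(adc$data, 256, 99)), 2, var))
#> [1] 8.64e-39
```

The b200 series tracks the regressor almost perfectly (|r| = 0.999 — it is
T2-weighted), while the ADC series computed from the very same volumes has
zero temporal variance to machine precision: the shared T2 factor cancels in
the pair ratio.

On the default synthetic 8-subject breath-hold cohort
(`analysis/05_lag_mapping.R`), the median percentage of voxels with
z_max > 3.09 is

```
BOLD 99.1 > b200 68.5 > b1000 27.3 > ADC 1.1
```

— strong vascular coupling in BOLD, progressively weaker residual T2
weighting in the diffusion series, and ADC at the false-positive floor. The
grey-matter-normalized white-matter median latency is +2.5 s, recovering the
generator's GM/WM vascular delay exactly at the 0.5 s lag-grid resolution.

## Analysis workflow

The numbered scripts under `analysis/` run the study end to end and write
tables under `results/`:

```
01_simulate_cohort.R    02_physio_regressors.R   03_contrast_timeseries.R
04_conditioning_qc.R    05_lag_mapping.R         06_surrogate_null.R
07_group_stats.R
```

Each is a thin driver over the package functions; `run_pipeline()` sequences
the same stages programmatically from a single `pipeline_config()`.

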