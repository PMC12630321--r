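#!/usr/bin/env Rscript
# Build the four analysis timeseries (BOLD, b200, b1000, ADC) for one subject
# and demonstrate the T2-suppression mechanism of the two-point ADC, plus the
# three-compartment CSF partial-volume estimate.

suppressPackageStartupMessages(library(petco2lag))
dir.create("results/contrast", recursive = TRUE, showWarnings = FALSE)

# Noiseless coupled diffusion run: the T2 modulation drives both b-value
# series but cancels exactly in the ADC ratio.
tr <- generate_co2_trace(resting_spec(220), seed = 11)
masks <- make_masks(c(8, 8, 4))
gt <- make_ground_truth(c(8, 8, 4), masks$GM, masks$WM,
                        noise_sigma = 0, ivim_fraction = 0)
dw <- generate_fmri_run("dfmri", gt, make_vascular_driver(tr),
                        TR_s = 1.1, n_pairs = 99, seed = 12)
sp <- split_dfmri(dw)
adc <- compute_adc_series(dw)
reg <- process_co2(tr)

X <- t(matrix(adc$data, prod(dim(adc$data)[1:3]), dim(adc$data)[4]))
m200 <- xcorr_map(sp$b200, reg)
m1000 <- xcorr_map(sp$b1000, reg)
cat("Noiseless coupled run:\n")
cat("  b200  |r| with pETCO2:", round(range(abs(m200$rmax)), 4), "\n")
cat("  b1000 |r| with pETCO2:", round(range(abs(m1000$rmax)), 4), "\n")
cat("  ADC temporal variance (mm^2/s)^2:", max(apply(X, 2, var)),
    "- zero to machine precision: the shared T2 factor cancels in the ratio.\n")

tab <- data.frame(series = c("b200", "b1000", "ADC"),
                  min_abs_r = c(min(abs(m200$rmax)), min(abs(m1000$rmax)), NA),
                  max_temporal_var = c(NA, NA, max(apply(X, 2, var))))
write.table(tab, "results/contrast/t2_suppression.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# CSF partial-volume effect: how much ADC change a -0.6 point CSF volume
# fraction shift could produce under the three-compartment model.
sw <- csf_pve_sweep(delta_f_csf = -0.006)
write.table(sw$table, "results/contrast/csf_pve_sweep.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("CSF partial-volume sweep (CSF fraction 0.02-0.50): extremum %.3f%%\n",
            100 * sw$extremum))
cat("Even the worst case stays a fraction of a percent, so Monro-Kellie CSF\n")
cat("compensation cannot explain percent-level ADC responses.\n")
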