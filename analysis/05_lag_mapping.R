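#!/usr/bin/env Rscript
# Voxelwise lagged correlation maps for the breath-hold cohort: per-contrast
# zmax maps at the fixed z = 3.09 threshold, grey-matter-normalized latency
# maps, and the mean correlation profiles over significant voxels.

suppressPackageStartupMessages(library(petco2lag))
dir.create("results/lagmap", recursive = TRUE, showWarnings = FALSE)
seed <- 1

cohort <- simulate_cohort(n_subjects = 8, condition = "breathhold", seed = seed)
zthr <- round(breathhold_z_threshold(0.001), 2)
metrics <- list(); profiles <- list(); latencies <- list()

for (sub in cohort) {
  reg <- process_co2(sub$trace)
  sp <- split_dfmri(sub$runs$dfmri)
  series <- list(BOLD = sub$runs$BOLD, b200 = sp$b200, b1000 = sp$b1000,
                 ADC = compute_adc_series(sub$runs$dfmri))
  for (ct in names(series)) {
    run <- highpass_temporal(smooth_spatial(series[[ct]]))
    m <- xcorr_map(run, reg, keep_profiles = TRUE)
    m <- normalize_latency(m, sub$masks$GM)
    metrics[[length(metrics) + 1]] <- data.frame(
      subject = sub$subject, contrast = ct,
      pct_significant = percent_significant(m, run$masks$brain, zthr),
      mean_r2 = mean_variance_explained(m, run$masks$brain),
      gm_shift_s = m$latency_shift_s)
    sig <- m$valid & m$zmax > zthr
    if (any(sig)) {
      pr <- correlation_profile(m, sig)
      pr$subject <- sub$subject; pr$contrast <- ct
      profiles[[length(profiles) + 1]] <- pr
    }
    if (ct == "BOLD")
      latencies[[length(latencies) + 1]] <- data.frame(
        subject = sub$subject,
        gm_median = median(m$latency_s[sub$masks$GM & m$valid]),
        wm_median = median(m$latency_s[sub$masks$WM & m$valid]))
  }
}

met <- do.call(rbind, metrics)
write.table(met, "results/lagmap/metrics.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
prof_tab <- do.call(rbind, profiles)
prof_tab$mean_r <- round(prof_tab$mean_r, 5)
write.table(prof_tab, "results/lagmap/profiles.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
lat <- do.call(rbind, latencies)
write.table(lat, "results/lagmap/bold_latencies.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Median percent-significant at z >", zthr, "by contrast:\n")
print(aggregate(pct_significant ~ contrast, met, median))
cat("BOLD latency after grey-matter normalization: WM median",
    median(lat$wm_median), "s (truth: +2.5 s relative to GM).\n")
cat("The ordering BOLD > b200 > b1000 > ADC reflects progressively weaker\n")
cat("vascular (T2) weighting; the ADC series sits near the false-positive floor.\n")
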