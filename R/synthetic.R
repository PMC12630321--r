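#' Breath-hold paradigm
#'
#' Describes a cued breath-hold run: `n_epochs` repetitions of
#' baseline breathing, a breath hold, and recovery breathing. The default
#' timings (18 s baseline, 14 s hold, 16 s recovery) give a 48 s epoch and a
#' 192 s run. The baseline block ends with a cued 2 s inhale + 2 s exhale and
#' the recovery block opens with a cued 2 s exhale; those cues are contained
#' in the stated durations.
#'
#' @param n_epochs number of task epochs (>= 1).
#' @param timings numeric length-3: baseline, hold, recovery durations (s).
#' @return an object of class `breathhold_paradigm` with fields `n_epochs`,
#'   `baseline_s`, `hold_s`, `recovery_s`, `epoch_duration_s`,
#'   `run_duration_s`.
#' @export
generate_breathhold_paradigm <- function(n_epochs = 4, timings = c(18, 14, 16)) {
  if (!is.numeric(n_epochs) || length(n_epochs) != 1 || n_epochs < 1)
    stop("n_epochs must be a count >= 1", call. = FALSE)
  if (length(timings) != 3 || any(!is.finite(timings)) || any(timings <= 0))
    stop("timings must be three positive durations (s)", call. = FALSE)
  n_epochs <- as.integer(n_epochs)
  structure(list(
    n_epochs = n_epochs,
    baseline_s = timings[1], hold_s = timings[2], recovery_s = timings[3],
    epoch_duration_s = sum(timings),
    run_duration_s = n_epochs * sum(timings)
  ), class = "breathhold_paradigm")
}

#' @export
print.breathhold_paradigm <- function(x, ...) {
  cat(sprintf("Breath-hold paradigm: %d x [%g s rest | %g s hold | %g s rest] = %g s\n",
              x$n_epochs, x$baseline_s, x$hold_s, x$recovery_s, x$run_duration_s))
  invisible(x)
}

# Hold windows [start, end) in task time (s), one row per epoch.
hold_windows <- function(paradigm) {
  e <- paradigm$epoch_duration_s
  starts <- (seq_len(paradigm$n_epochs) - 1) * e + paradigm$baseline_s
  cbind(start = starts, end = starts + paradigm$hold_s)
}

#' Boxcar hold indicator
#'
#' Samples a 0/1 indicator of the breath-hold windows at `fs_hz`, over the
#' full run, on the grid `t = k / fs_hz`, `k = 0, ..., fs*duration - 1`.
#' A sample is inside a hold if `start <= t < end`.
#'
#' @param paradigm a [generate_breathhold_paradigm()] object.
#' @param fs_hz sampling rate (Hz).
#' @return numeric vector of 0/1 values.
#' @export
hold_indicator <- function(paradigm, fs_hz) {
  t <- seq(0, paradigm$run_duration_s - 1 / fs_hz, by = 1 / fs_hz)
  w <- hold_windows(paradigm)
  ind <- rep(0, length(t))
  for (i in seq_len(nrow(w))) ind[t >= w[i, 1] & t < w[i, 2]] <- 1
  ind
}

#' Resting-state run specification
#'
#' @param duration_s run duration in seconds (default 880 s = 14 min 40 s).
#' @export
resting_spec <- function(duration_s = 880) {
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be positive", call. = FALSE)
  structure(list(run_duration_s = duration_s), class = "resting_spec")
}

# End-tidal envelope truth E(t) in "mouth time" (t = 0 at scan trigger).
# Breath-hold: baseline plus, per epoch, a hold_delta pulse that reaches its
# full height at the first post-hold end-tidal peak (`first_peak_delay_s`
# after the hold ends, the cued post-hold exhale) and decays exponentially
# over the recovery breathing. Resting: a band-limited Gaussian-like process,
# power confined below 0.05 Hz.
make_envelope_fun <- function(spec, petco2_baseline_mmHg, hold_delta_mmHg,
                              fluctuation_sd_mmHg, recovery_tau_s = 8,
                              first_peak_delay_s = 0) {
  if (inherits(spec, "breathhold_paradigm")) {
    w <- hold_windows(spec)
    function(t) {
      v <- rep(petco2_baseline_mmHg, length(t))
      for (i in seq_len(nrow(w))) {
        t_pk <- w[i, 2] + first_peak_delay_s
        dt <- t - t_pk
        ramp <- pmin(pmax((t - w[i, 2]) / max(first_peak_delay_s, 1e-9), 0), 1)
        v <- v + hold_delta_mmHg * ifelse(dt >= 0, exp(-dt / recovery_tau_s), ramp)
      }
      v
    }
  } else {
    # Sum of sinusoids with frequencies in (0.004, 0.045) Hz; weights scaled
    # so the process SD equals fluctuation_sd_mmHg (SD of a sinusoid sum is
    # sqrt(sum(a^2)/2) over long windows).
    n_comp <- 12
    freqs <- stats::runif(n_comp, 0.004, 0.045)
    phases <- stats::runif(n_comp, 0, 2 * pi)
    w <- abs(stats::rnorm(n_comp)) + 0.2
    a <- w * fluctuation_sd_mmHg / sqrt(sum(w^2) / 2)
    function(t) {
      v <- rep(petco2_baseline_mmHg, length(t))
      for (i in seq_len(n_comp)) v <- v + a[i] * sin(2 * pi * freqs[i] * t + phases[i])
      v
    }
  }
}

#' Generate a raw expired-CO2 trace
#'
#' Emulates a gas-analyser recording of expired CO2 via nasal cannula. Each
#' breath cycle rises to an end-tidal plateau at the end of the exhale and
#' falls to near zero during inhalation, giving unambiguous end-tidal peaks.
#' In breath-hold mode no exhalation occurs inside the hold windows and the
#' first post-hold peak is elevated by approximately `hold_delta_mmHg`
#' (decaying over the recovery period). In resting mode the end-tidal
#' envelope is a band-limited random process with power below 0.05 Hz.
#'
#' The recording starts `pre_s` seconds before the scan trigger and continues
#' `post_s` seconds after the run ends (as acquired in practice, to allow
#' temporal shifting). Gas transport through the sampling line delays the
#' recorded trace by `transport_delay_s` relative to the physiological events
#' at the mouth; recovered fMRI-vs-regressor latencies therefore centre
#' around `-(transport_delay_s - voxel latency)`.
#'
#' @param spec a `breathhold_paradigm` or `resting_spec`.
#' @param breath_period_s breath cycle duration (s), in `[2, 10]`.
#' @param petco2_baseline_mmHg baseline end-tidal pressure (mmHg).
#' @param hold_delta_mmHg end-tidal elevation of the first post-hold breath.
#' @param fluctuation_sd_mmHg SD of the resting end-tidal envelope (mmHg).
#' @param fs_hz recording sampling rate (>= 10 Hz).
#' @param transport_delay_s gas-analyser transport delay (s).
#' @param pre_s,post_s recording margins before trigger / after run end (s).
#' @param noise_sd_mmHg additive Gaussian measurement noise SD.
#' @param seed integer seed for reproducibility.
#' @return an object of class `co2_trace`: `fs_hz`, `values`,
#'   `start_offset_s` (time of first sample relative to the first volume),
#'   `times_s`, `transport_delay_s`, and a `truth` list with the end-tidal
#'   peak times/values, the recorded-time envelope at 50 Hz, the mouth-time
#'   envelope at 50 Hz (used to drive fMRI generation), and hold windows.
#' @export
generate_co2_trace <- function(spec, breath_period_s = 5,
                               petco2_baseline_mmHg = 40, hold_delta_mmHg = 8,
                               fluctuation_sd_mmHg = 2, fs_hz = 100,
                               transport_delay_s = 15, pre_s = 20, post_s = 30,
                               noise_sd_mmHg = 0, seed = NULL) {
  if (fs_hz < 10) stop("fs_hz must be >= 10 Hz", call. = FALSE)
  if (breath_period_s < 2 || breath_period_s > 10)
    stop("breath_period_s must lie in [2, 10] s", call. = FALSE)
  is_bh <- inherits(spec, "breathhold_paradigm")
  if (!is_bh && !inherits(spec, "resting_spec"))
    stop("spec must be a breathhold_paradigm or resting_spec", call. = FALSE)
  if (is_bh && spec$hold_s >= spec$run_duration_s)
    stop("hold duration exceeds the run duration", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  dur <- spec$run_duration_s
  P <- breath_period_s
  env_fun <- make_envelope_fun(spec, petco2_baseline_mmHg, hold_delta_mmHg,
                               fluctuation_sd_mmHg, first_peak_delay_s = P / 2)
  holds <- if (is_bh) hold_windows(spec) else matrix(numeric(0), 0, 2)

  trough <- 2                          # inspiratory CO2 level (mmHg)
  # Recorded-time grid and the corresponding mouth-time grid.
  u <- seq(-pre_s, dur + post_s, by = 1 / fs_hz)
  tm <- u - transport_delay_s
  # Breathing segments between holds; cycles restart at each segment start,
  # so the first post-hold exhale (the cued 2 s exhale of the paradigm) comes
  # immediately after the hold and carries the full hold_delta elevation.
  bounds <- c(min(tm), as.vector(t(holds)), max(tm))
  v <- rep(trough, length(u))
  cyc_peak_t <- numeric(0); cyc_val <- numeric(0)
  for (si in seq(1, length(bounds) - 1, by = 2)) {
    seg0 <- bounds[si]; seg1 <- bounds[si + 1]
    K <- floor((seg1 - seg0) / P)
    if (K < 1) next
    sel <- which(tm >= seg0 & tm < seg0 + K * P)
    tau <- tm[sel] - seg0
    k <- floor(tau / P)
    centers <- seg0 + (0:(K - 1)) * P + P / 2
    vals <- env_fun(centers)
    frac <- tau / P - k
    # Raised-cosine breath cycle: CO2 rises through the exhale to a single
    # unambiguous end-tidal peak at mid-cycle and falls back to the
    # inspiratory trough. The cycle has a single spectral line at 1/P Hz
    # (well below the 1 Hz detection low-pass), so filtered peak values
    # equal the truth to numerical precision.
    v[sel] <- trough + (vals[k + 1L] - trough) * (1 - cos(2 * pi * frac)) / 2
    cyc_peak_t <- c(cyc_peak_t, centers)
    cyc_val <- c(cyc_val, vals)
  }
  if (noise_sd_mmHg > 0) v <- v + stats::rnorm(length(v), 0, noise_sd_mmHg)
  # Drop edge cycles clipped by the recording window.
  keep <- (cyc_peak_t - P / 2) >= min(tm) & (cyc_peak_t + P / 2) <= max(tm)
  f50 <- 50
  t50_rec <- seq(-pre_s, dur + post_s, by = 1 / f50)
  t50_mouth <- seq(min(tm), max(tm), by = 1 / f50)
  structure(list(
    fs_hz = fs_hz, values = v, start_offset_s = -pre_s, times_s = u,
    transport_delay_s = transport_delay_s, run_duration_s = dur,
    truth = list(
      peak_times_s = cyc_peak_t[keep] + transport_delay_s,
      peak_values_mmHg = cyc_val[keep],
      envelope_recorded = list(t0 = t50_rec[1], fs_hz = f50,
                               values = env_fun(t50_rec - transport_delay_s)),
      envelope_mouth = list(t0 = t50_mouth[1], fs_hz = f50,
                            values = env_fun(t50_mouth)),
      hold_windows_recorded = holds + transport_delay_s,
      spec = spec)
  ), class = "co2_trace")
}

#' Ground-truth vascular driver
#'
#' Builds the waveform that couples arterial CO2 to the MRI signal in the
#' generator: the mouth-time end-tidal envelope, cubic-detrended and
#' convolved with the canonical double-gamma HRF normalized to unit area
#' (so the driver keeps mmHg units). Voxel signals are generated from this
#' driver delayed by the voxel's latency.
#'
#' @param trace a [generate_co2_trace()] object.
#' @return class `vascular_driver`: list(`t0`, `fs_hz`, `values`).
#' @export
make_vascular_driver <- function(trace) {
  env <- trace$truth$envelope_mouth
  x <- env$values
  t <- env$t0 + (seq_along(x) - 1) / env$fs_hz
  x <- stats::lm.fit(cbind(1, stats::poly(t, 3)), x)$residuals
  h <- hrf_double_gamma(dt = 1 / env$fs_hz, normalize = "area")
  y <- stats::convolve(x, rev(h), type = "open")[seq_along(x)]
  structure(list(t0 = env$t0, fs_hz = env$fs_hz, values = y),
            class = "vascular_driver")
}

# Evaluate a driver at arbitrary times (NA outside its support).
driver_at <- function(driver, t) {
  interp_uniform(driver$values, driver$t0, 1 / driver$fs_hz, t)
}

#' Two-compartment diffusion-weighted signal fraction
#'
#' Normalized signal `(1 - f) exp(-b ADC) + f exp(-b D*)` of a tissue
#' compartment with diffusivity `adc` plus an IVIM pseudo-diffusion
#' compartment of volume fraction `f` and coefficient `dstar`.
#'
#' @param b b-value (s/mm^2); `adc`, `dstar` in mm^2/s; `f` in `[0, 1)`.
#' @export
dw_signal <- function(b, adc, f = 0, dstar = 10e-3) {
  (1 - f) * exp(-b * adc) + f * exp(-b * dstar)
}

#' Ground truth for synthetic fMRI runs
#'
#' Per-voxel coupling parameters and scalar signal-model constants for the
#' generator. Vascular coupling amplitude is in signal fraction per mmHg of
#' driver; latencies in seconds (>= 0); `S0` is the equilibrium signal, the
#' baseline image intensity being `S0 * exp(-TE_s / T2_baseline_s)`.
#'
#' @param dims 3D grid dimensions.
#' @param gm_mask,wm_mask logical 3D arrays (disjoint).
#' @param amp_gm,amp_wm vascular amplitude in GM / WM (fraction per mmHg).
#' @param lat_gm_s,lat_wm_s vascular latency in GM / WM (s).
#' @param noise_sigma additive Gaussian noise SD (signal units).
#' @param S0,TE_s,T2_baseline_s spin-echo signal model constants.
#' @param adc_baseline baseline ADC (mm^2/s).
#' @param ivim_fraction,ivim_dstar IVIM pseudo-diffusion fraction and
#'   coefficient (mm^2/s).
#' @param neural_adc_amplitude optional 3D array of fractional ADC response
#'   gain; `neural_adc_timecourse` optional list(`t0`, `fs_hz`, `values`).
#' @return class `ground_truth`.
#' @export
make_ground_truth <- function(dims, gm_mask, wm_mask,
                              amp_gm = 0.004, amp_wm = 0.002,
                              lat_gm_s = 1.0, lat_wm_s = 3.5,
                              noise_sigma = 10,
                              S0 = 2000, TE_s = 0.105, T2_baseline_s = 0.08,
                              adc_baseline = 0.8e-3,
                              ivim_fraction = 0.01, ivim_dstar = 10e-3,
                              neural_adc_amplitude = NULL,
                              neural_adc_timecourse = NULL) {
  amp <- array(0, dims); amp[gm_mask] <- amp_gm; amp[wm_mask] <- amp_wm
  lat <- array(0, dims); lat[gm_mask] <- lat_gm_s; lat[wm_mask] <- lat_wm_s
  gt <- structure(list(
    dims = dims, gm_mask = gm_mask, wm_mask = wm_mask,
    vascular_amplitude = amp, latency_field = lat,
    neural_adc_amplitude = neural_adc_amplitude,
    neural_adc_timecourse = neural_adc_timecourse,
    noise_sigma = noise_sigma, S0 = S0, TE_s = TE_s,
    T2_baseline_s = T2_baseline_s, adc_baseline = adc_baseline,
    ivim_fraction = ivim_fraction, ivim_dstar = ivim_dstar
  ), class = "ground_truth")
  validate_ground_truth(gt)
  gt
}

validate_ground_truth <- function(gt) {
  if (any(gt$latency_field < 0)) stop("latency_field must be >= 0", call. = FALSE)
  if (gt$ivim_fraction < 0 || gt$ivim_fraction >= 1)
    stop("ivim_fraction must lie in [0, 1)", call. = FALSE)
  if (gt$adc_baseline <= 0) stop("adc_baseline must be > 0", call. = FALSE)
  if (gt$noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  invisible(gt)
}

# Driver values delayed per voxel: rows = time points, cols = voxels.
delayed_driver_matrix <- function(driver, times, lat_vec) {
  n <- length(driver$values)
  D <- matrix(0, length(times), length(lat_vec))
  pos <- outer(times, lat_vec, "-")           # t - latency, per voxel
  idx <- (pos - driver$t0) * driver$fs_hz + 1
  idx[idx < 1] <- 1; idx[idx > n] <- n
  i0 <- floor(idx); i0[i0 == n] <- n - 1
  w <- idx - i0
  D[] <- driver$values[i0] * (1 - w) + driver$values[i0 + 1] * w
  D
}

#' Generate a synthetic fMRI run
#'
#' BOLD mode: per-voxel signal `A0 * (1 + amp * d(t - latency)) + noise`,
#' `A0 = S0 exp(-TE / T2_baseline)`. Diffusion mode: volumes follow
#' `S(b, t) = A0 * m(t) * [(1 - f) exp(-b ADC(t)) + f exp(-b D*)] + noise`,
#' with a b-schedule of two b = 0 volumes followed by alternating
#' b = 200 / 1000 s/mm^2 volumes. The vascular T2 modulation
#' `m(t) = 1 + amp * d(t - latency)` is sampled once per interleaved pair at
#' the pair midpoint (the driver is band-limited below 0.05 Hz, so within-pair
#' variation is negligible), which makes the two-point ADC exactly free of
#' shared T2 modulation. `ADC(t) = adc_baseline * (1 + neural response)`.
#'
#' Volume times are acquisition mid-times `(i - 0.5) * TR`.
#'
#' @param contrast "BOLD" or "dfmri".
#' @param gt a [make_ground_truth()] object.
#' @param driver a [make_vascular_driver()] object (or any list with
#'   `t0`, `fs_hz`, `values`).
#' @param TR_s repetition time (s).
#' @param n_vols number of volumes (BOLD) — for dfmri give `n_pairs` instead.
#' @param n_pairs number of interleaved b200/b1000 pairs (dfmri mode).
#' @param voxel_size_mm isotropic voxel size.
#' @param store_noiseless keep the noiseless array in `truth` (for SNR and
#'   recovery tests).
#' @param seed integer seed.
#' @return an [fmri_run()] object; `$truth` holds the ground truth used,
#'   the driver, and optionally the noiseless data.
#' @export
generate_fmri_run <- function(contrast = c("BOLD", "dfmri"), gt, driver,
                              TR_s = 1, n_vols = 192, n_pairs = 96,
                              voxel_size_mm = 2.8, store_noiseless = FALSE,
                              seed = NULL) {
  contrast <- match.arg(contrast)
  if (!is.null(seed)) set.seed(seed)
  dims <- gt$dims
  nvox <- prod(dims)
  A0 <- gt$S0 * exp(-gt$TE_s / gt$T2_baseline_s)
  amp <- as.vector(gt$vascular_amplitude)
  lat <- as.vector(gt$latency_field)
  masks <- list(brain = array(TRUE, dims), GM = gt$gm_mask, WM = gt$wm_mask)

  if (contrast == "BOLD") {
    times <- (seq_len(n_vols) - 0.5) * TR_s
    D <- delayed_driver_matrix(driver, times, lat)
    S <- A0 * (1 + sweep(D, 2, amp, "*"))            # time x voxel
    b_schedule <- NULL
  } else {
    n_vols <- 2L + 2L * n_pairs
    times <- (seq_len(n_vols) - 0.5) * TR_s
    b_schedule <- c(0, 0, rep(c(200, 1000), n_pairs))
    pair_mid <- (times[seq(3, n_vols, by = 2)] + times[seq(4, n_vols, by = 2)]) / 2
    M <- 1 + sweep(delayed_driver_matrix(driver, pair_mid, lat), 2, amp, "*")
    a_t <- rep(0, n_pairs)
    adc_amp <- rep(0, nvox)
    if (!is.null(gt$neural_adc_amplitude)) {
      adc_amp <- as.vector(gt$neural_adc_amplitude)
      tc <- gt$neural_adc_timecourse
      a_t <- interp_uniform(tc$values, tc$t0, 1 / tc$fs_hz, pair_mid)
      a_t[is.na(a_t)] <- 0
    }
    ADC <- gt$adc_baseline * (1 + outer(a_t, adc_amp))  # pair x voxel
    f <- gt$ivim_fraction; ds <- gt$ivim_dstar
    S <- matrix(0, n_vols, nvox)
    Mb0 <- 1 + sweep(delayed_driver_matrix(driver, times[1:2], lat), 2, amp, "*")
    S[1:2, ] <- A0 * Mb0
    S[seq(3, n_vols, by = 2), ] <- A0 * M * ((1 - f) * exp(-200 * ADC) + f * exp(-200 * ds))
    S[seq(4, n_vols, by = 2), ] <- A0 * M * ((1 - f) * exp(-1000 * ADC) + f * exp(-1000 * ds))
  }

  noiseless <- if (store_noiseless) array(t(S), dim = c(dims, n_vols)) else NULL
  if (gt$noise_sigma > 0) S <- S + stats::rnorm(length(S), 0, gt$noise_sigma)
  run <- fmri_run(data = array(t(S), dim = c(dims, n_vols)), TR_s = TR_s,
                  contrast = if (contrast == "BOLD") "BOLD" else "dfmri",
                  b_schedule = b_schedule, volume_times_s = times,
                  masks = masks, voxel_size_mm = voxel_size_mm)
  run$truth <- list(gt = gt, driver = driver, noiseless = noiseless)
  run
}

#' Generate a synthetic head-motion trace
#'
#' One 6-vector per volume: 3 translations (mm) then 3 rotations (rad).
#' Translations combine a linear drift (reaching `drift_mm` on the first axis
#' by the last volume) with white jitter of SD `jitter_mm` on each axis;
#' rotations get white jitter of SD `rot_jitter_rad`. Optional spikes add a
#' one-volume translation displacement.
#'
#' @param n_vols number of volumes (>= 2).
#' @param drift_mm,jitter_mm,rot_jitter_rad motion magnitudes.
#' @param spikes optional data.frame with columns `volume`, `magnitude_mm`.
#' @param seed integer seed.
#' @return class `motion_trace`: an `n_vols x 6` matrix.
#' @export
generate_motion <- function(n_vols, drift_mm = 0, jitter_mm = 0,
                            rot_jitter_rad = 0, spikes = NULL, seed = NULL) {
  if (n_vols < 2) stop("n_vols must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(0, n_vols, 6,
              dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                      "rot_x", "rot_y", "rot_z")))
  M[, 1] <- seq(0, drift_mm, length.out = n_vols)
  if (jitter_mm > 0)
    M[, 1:3] <- M[, 1:3] + matrix(stats::rnorm(3 * n_vols, 0, jitter_mm), n_vols)
  if (rot_jitter_rad > 0)
    M[, 4:6] <- matrix(stats::rnorm(3 * n_vols, 0, rot_jitter_rad), n_vols)
  if (!is.null(spikes))
    for (i in seq_len(nrow(spikes)))
      M[spikes$volume[i], 1] <- M[spikes$volume[i], 1] + spikes$magnitude_mm[i]
  if (any(!is.finite(M))) stop("motion trace contains non-finite values", call. = FALSE)
  structure(M, class = c("motion_trace", "matrix"))
}

#' Translation jitter SD achieving a target mean framewise displacement
#'
#' For white translation jitter of SD `j` on three axes (no rotations), the
#' volume-to-volume difference on each axis is N(0, 2 j^2), so
#' E(FD) = 3 * E|N(0, 2 j^2)| = 6 j / sqrt(pi). Inverting gives the jitter
#' that calibrates the generator to a desired mean FD.
#'
#' @param mean_fd_mm target mean framewise displacement (mm).
#' @export
jitter_for_mean_fd <- function(mean_fd_mm) mean_fd_mm * sqrt(pi) / 6

#' Simple tissue masks for the synthetic grid
#'
#' Splits the grid into grey matter (first `gm_frac` of the x axis) and white
#' matter (the rest); the brain mask covers the whole grid.
#'
#' @param dims 3D dimensions; `gm_frac` GM fraction along x.
#' @return list(`brain`, `GM`, `WM`) of logical 3D arrays.
#' @export
make_masks <- function(dims, gm_frac = 0.5) {
  gm <- array(FALSE, dims); wm <- array(FALSE, dims)
  cut <- round(dims[1] * gm_frac)
  gm[seq_len(cut), , ] <- TRUE
  wm[(cut + 1):dims[1], , ] <- TRUE
  list(brain = array(TRUE, dims), GM = gm, WM = wm)
}

#' Simulate a multi-subject, multi-contrast synthetic cohort
#'
#' The default settings are the study conditions used throughout the tests
#' and the acceptance analysis: per subject, a CO2 recording (breath-hold,
#' 4 x [18, 14, 16] s epochs, or resting, 880 s), one BOLD run and one
#' interleaved b200/b1000 diffusion run on a 20 x 20 x 10 grid, with strong
#' vascular coupling into the T2-weighted signals (spin-echo coupling 0.7 x
#' the gradient-echo BOLD coupling), no vascular coupling into ADC beyond a
#' static IVIM compartment, white-matter vascular latency 2.5 s later than
#' grey matter, and additive thermal noise.
#'
#' @param n_subjects cohort size.
#' @param condition "breathhold" or "resting".
#' @param dims 3D grid.
#' @param seed master seed; subject s uses `seed + 1000 * s` offsets.
#' @param contrasts which acquisitions to generate ("BOLD", "dfmri").
#' @param TR_s repetition time (s); defaults 1 s (breath-hold), 1.1 s (rest).
#' @param amp_gm_bold GM BOLD coupling (fraction per mmHg).
#' @param se_coupling spin-echo (diffusion) coupling relative to BOLD.
#' @param noise_sigma additive noise SD.
#' @param lat_gm_s,lat_wm_s vascular latencies (s).
#' @param store_noiseless keep noiseless arrays in run truth.
#' @return list of subjects; each has `trace`, `driver`, `runs` (named list
#'   of [fmri_run()]), `masks`, and the ground truths used.
#' @export
simulate_cohort <- function(n_subjects = 8,
                            condition = c("breathhold", "resting"),
                            dims = c(20, 20, 10), seed = 1,
                            contrasts = c("BOLD", "dfmri"),
                            TR_s = NULL,
                            amp_gm_bold = 0.004, se_coupling = 0.7,
                            noise_sigma = 10,
                            lat_gm_s = 1.0, lat_wm_s = 3.5,
                            store_noiseless = FALSE) {
  condition <- match.arg(condition)
  if (is.null(TR_s)) TR_s <- if (condition == "breathhold") 1.0 else 1.1
  spec <- if (condition == "breathhold") generate_breathhold_paradigm()
          else resting_spec()
  masks <- make_masks(dims)
  lapply(seq_len(n_subjects), function(s) {
    sseed <- seed + 1000L * s
    trace <- generate_co2_trace(spec, seed = sseed)
    driver <- make_vascular_driver(trace)
    n_bold <- floor(spec$run_duration_s / TR_s)
    n_pairs <- floor((n_bold - 2) / 2)
    runs <- list()
    if ("BOLD" %in% contrasts) {
      gt_bold <- make_ground_truth(dims, masks$GM, masks$WM,
                                   amp_gm = amp_gm_bold, amp_wm = amp_gm_bold / 2,
                                   lat_gm_s = lat_gm_s, lat_wm_s = lat_wm_s,
                                   noise_sigma = noise_sigma)
      runs$BOLD <- generate_fmri_run("BOLD", gt_bold, driver, TR_s = TR_s,
                                     n_vols = n_bold, seed = sseed + 1,
                                     store_noiseless = store_noiseless)
    }
    if ("dfmri" %in% contrasts) {
      gt_dw <- make_ground_truth(dims, masks$GM, masks$WM,
                                 amp_gm = amp_gm_bold * se_coupling,
                                 amp_wm = amp_gm_bold * se_coupling / 2,
                                 lat_gm_s = lat_gm_s, lat_wm_s = lat_wm_s,
                                 noise_sigma = noise_sigma)
      runs$dfmri <- generate_fmri_run("dfmri", gt_dw, driver, TR_s = TR_s,
                                      n_pairs = n_pairs, seed = sseed + 2,
                                      store_noiseless = store_noiseless)
    }
    list(subject = s, condition = condition, trace = trace, driver = driver,
         runs = runs, masks = masks, seed = sseed)
  })
}
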