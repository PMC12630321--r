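#' Low-pass filter a raw CO2 trace
#'
#' Zero-phase (forward-backward) Butterworth low-pass, default 1 Hz cutoff
#' and 4th order, applied before end-tidal peak detection. Zero-phase
#' filtering is used so that no artificial lag enters the latency pipeline.
#'
#' @param trace a `co2_trace` (or any list with `fs_hz`, `values`).
#' @param cutoff_hz cutoff frequency (Hz), must be below Nyquist.
#' @param order filter order.
#' @return the trace with filtered `values` and a `provenance` entry.
#' @export
lowpass_co2 <- function(trace, cutoff_hz = 1, order = 4) {
  co <- butter_coefs(order, cutoff_hz, trace$fs_hz, "low")
  trace$values <- filtfilt_vec(co$b, co$a, trace$values,
                               npad = ceiling(3 * trace$fs_hz / cutoff_hz))
  trace$provenance <- c(trace$provenance,
                        list(lowpass = list(cutoff_hz = cutoff_hz, order = order,
                                            zero_phase = TRUE)))
  trace
}

# Local maxima with plateau handling (plateau -> centre index).
find_local_maxima <- function(x) {
  dx <- diff(x)
  nz <- which(dx != 0)
  if (length(nz) < 2) return(integer(0))
  sgn <- sign(dx[nz])
  chg <- which(sgn[-length(sgn)] > 0 & sgn[-1] < 0)
  start <- nz[chg] + 1L       # last sample of the rising edge
  end <- nz[chg + 1L]         # sample before the falling edge
  as.integer(floor((start + end) / 2))
}

# Topographic prominence (scipy convention): for each peak, walk left and
# right to the nearest sample higher than the peak (or the edge), take the
# minimum on each side; prominence = peak - max(left min, right min).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    v <- x[p]
    li <- which(x[seq_len(p - 1)] > v)
    lo <- if (length(li)) max(li) + 1L else 1L
    ri <- which(x[(p + 1):length(x)] > v)
    hi <- if (length(ri)) p + min(ri) - 1L else length(x)
    v - max(min(x[lo:p]), min(x[p:hi]))
  }, numeric(1))
}

#' Detect end-tidal peaks in a low-pass-filtered CO2 trace
#'
#' Finds exhalation end-tidal peaks: local maxima with a minimum topographic
#' prominence, separated by at least `min_interval_s`, followed by an
#' automatic outlier-rejection rule that replaces manual review: peak heights
#' are compared against a moving median (window `median_window` peaks), and
#' peaks deviating by more than `outlier_mad_k` robust SDs are rejected. By
#' default only downward outliers are rejected (partial exhales read low;
#' genuinely elevated post-hold peaks must survive); set `two_sided = TRUE`
#' for symmetric rejection.
#'
#' @param trace low-pass-filtered `co2_trace`.
#' @param min_interval_s minimum separation between accepted peaks (s).
#' @param prominence_mmHg minimum prominence; default 10% of the trace IQR.
#' @param outlier_mad_k robust-SD multiple for rejection.
#' @param median_window moving-median window (odd number of peaks).
#' @param two_sided reject both high and low outliers.
#' @return integer sample indices of accepted peaks, with attribute
#'   `times_s` (recorded time) and `rejected` (indices removed as outliers).
#' @export
detect_end_tidal_peaks <- function(trace, min_interval_s = 2,
                                   prominence_mmHg = NULL, outlier_mad_k = 3,
                                   median_window = 7, two_sided = FALSE) {
  x <- trace$values
  if (is.null(prominence_mmHg))
    prominence_mmHg <- 0.1 * stats::IQR(x)
  cand <- find_local_maxima(x)
  if (length(cand)) {
    prom <- peak_prominence(x, cand)
    cand <- cand[prom >= prominence_mmHg]
  }
  if (!length(cand))
    stop("no end-tidal peaks found (check filtering and prominence)", call. = FALSE)
  # Enforce min separation, keeping higher peaks first.
  min_gap <- round(min_interval_s * trace$fs_hz)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) if (!length(kept) || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  kept <- sort(kept)
  # Moving-median outlier rejection of peak heights.
  rejected <- integer(0)
  if (length(kept) >= 3) {
    h <- x[kept]
    k <- min(median_window, length(h))
    if (k %% 2 == 0) k <- k - 1
    med <- if (k >= 3) stats::runmed(h, k, endrule = "median") else stats::median(h)
    dev <- h - med
    # Floor the robust scale at 5% of the typical peak height: genuine
    # breath-to-breath end-tidal variability is < ~10%, while partial exhales
    # read ~50% low, so the floor separates the two even on very regular
    # traces where the MAD collapses.
    scale <- max(stats::mad(dev), 0.05 * stats::median(h))
    bad <- if (two_sided) abs(dev) > outlier_mad_k * scale
           else dev < -outlier_mad_k * scale
    rejected <- kept[bad]
    kept <- kept[!bad]
  }
  if (!length(kept))
    stop("all detected peaks were rejected as outliers", call. = FALSE)
  structure(kept,
            times_s = trace$start_offset_s + (kept - 1) / trace$fs_hz,
            rejected = rejected)
}

#' Interpolate the end-tidal envelope at 50 Hz
#'
#' Piecewise-linear interpolation through the (peak time, peak value) pairs,
#' resampled at 50 Hz over the trace support; held constant at the nearest
#' peak value before the first and after the last peak.
#'
#' @param trace the (filtered) `co2_trace` the peaks were detected on.
#' @param peaks indices from [detect_end_tidal_peaks()].
#' @param fs_out output sampling rate (Hz).
#' @return class `petco2_envelope`: list(`fs_hz`, `times_s`, `values`,
#'   `peak_times_s`, `peak_values`).
#' @export
interpolate_petco2 <- function(trace, peaks, fs_out = 50) {
  if (length(peaks) < 2) stop("need at least 2 peaks to interpolate", call. = FALSE)
  pt <- trace$start_offset_s + (peaks - 1) / trace$fs_hz
  pv <- trace$values[peaks]
  n <- length(trace$values)
  t_out <- seq(trace$start_offset_s,
               trace$start_offset_s + (n - 1) / trace$fs_hz, by = 1 / fs_out)
  vals <- stats::approx(pt, pv, xout = t_out, rule = 2)$y
  structure(list(fs_hz = fs_out, times_s = t_out, values = vals,
                 peak_times_s = pt, peak_values = pv,
                 provenance = trace$provenance),
            class = "petco2_envelope")
}

#' Canonical double-gamma haemodynamic response function
#'
#' `h(t) = (t/d1)^a1 exp(-(t - d1)/b1) - r (t/d2)^a2 exp(-(t - d2)/b2)` with
#' response shape `a1 = 6`, scale `b1 = 1` s (peak at `d1 = a1 b1 = 6` s),
#' undershoot shape `a2 = 16`, scale `b2 = 1` s, undershoot ratio `r = 1/6`,
#' kernel length 32 s. Normalized to unit peak by default ("peak"; inert for
#' correlation analyses) or to unit discrete sum ("area"; convolution then
#' has unit gain, keeping physical units when the kernel drives generation).
#'
#' @param dt sample spacing (s).
#' @param duration_s kernel length (s).
#' @param a1,b1,a2,b2,ratio gamma parameters and undershoot ratio.
#' @param normalize "peak" or "area".
#' @return numeric kernel sampled at `t = 0, dt, ..., duration_s`.
#' @export
hrf_double_gamma <- function(dt = 0.02, duration_s = 32, a1 = 6, b1 = 1,
                             a2 = 16, b2 = 1, ratio = 1 / 6,
                             normalize = c("peak", "area")) {
  normalize <- match.arg(normalize)
  t <- seq(0, duration_s, by = dt)
  d1 <- a1 * b1; d2 <- a2 * b2
  h <- (t / d1)^a1 * exp(-(t - d1) / b1) - ratio * (t / d2)^a2 * exp(-(t - d2) / b2)
  if (normalize == "peak") h / max(h) else h / sum(h)  # unit discrete sum
}

#' Build the pETCO2 regressor
#'
#' Removes a least-squares cubic polynomial trend from the 50 Hz end-tidal
#' envelope, then causally convolves with the canonical double-gamma HRF
#' (sampled at the envelope rate), truncating to the input length. The
#' resulting detrended, convolved pETCO2 timeseries is the regressor used
#' for all lagged correlations.
#'
#' @param envelope a [interpolate_petco2()] object.
#' @param detrend_order polynomial detrend order (default cubic).
#' @param hrf optional HRF kernel; default [hrf_double_gamma()] at the
#'   envelope sampling rate, peak-normalized.
#' @param detrend set `FALSE` to bypass detrending (diagnostics only).
#' @return class `petco2_regressor`: list(`fs_hz`, `times_s`, `values`,
#'   `peak_times_s`, `provenance`).
#' @export
build_regressor <- function(envelope, detrend_order = 3, hrf = NULL,
                            detrend = TRUE) {
  x <- envelope$values
  t <- envelope$times_s
  if (is.null(hrf)) hrf <- hrf_double_gamma(dt = 1 / envelope$fs_hz)
  if (length(x) < length(hrf))
    stop("envelope is shorter than the HRF kernel", call. = FALSE)
  if (detrend)
    x <- stats::lm.fit(cbind(1, stats::poly(t, detrend_order)), x)$residuals
  y <- stats::convolve(x, rev(hrf), type = "open")[seq_along(x)]
  # the detrended input is zero-mean; remove the small truncation-edge offset
  if (detrend) y <- y - mean(y)
  structure(list(
    fs_hz = envelope$fs_hz, times_s = t, values = y,
    peak_times_s = envelope$peak_times_s,
    provenance = c(envelope$provenance,
                   list(detrend = list(order = detrend_order, applied = detrend),
                        hrf = list(model = "double-gamma", a1 = 6, b1 = 1,
                                   a2 = 16, b2 = 1, ratio = 1 / 6,
                                   duration_s = 32, normalize = "peak"),
                        peak_review = "automatic moving-median MAD rule"))
  ), class = "petco2_regressor")
}

#' Full CO2-to-regressor processing chain
#'
#' Convenience wrapper: low-pass filter, end-tidal peak detection,
#' 50 Hz envelope interpolation, cubic detrend + HRF convolution.
#'
#' @param trace a raw `co2_trace`.
#' @param ... passed to the individual stages.
#' @inheritParams lowpass_co2
#' @inheritParams detect_end_tidal_peaks
#' @return a `petco2_regressor`.
#' @export
process_co2 <- function(trace, cutoff_hz = 1, order = 4, min_interval_s = 2,
                        prominence_mmHg = NULL, outlier_mad_k = 3, ...) {
  f <- lowpass_co2(trace, cutoff_hz = cutoff_hz, order = order)
  p <- detect_end_tidal_peaks(f, min_interval_s = min_interval_s,
                              prominence_mmHg = prominence_mmHg,
                              outlier_mad_k = outlier_mad_k)
  env <- interpolate_petco2(f, p)
  build_regressor(env, ...)
}
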