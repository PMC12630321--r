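# Voxelwise lagged cross-correlation against the pETCO2 regressor, peak and
# latency extraction, Fisher-z maps, grey-matter latency normalization, and
# mean correlation profiles.

default_lags <- function() seq(-30, 0, by = 0.5)

# Regressor samples at (volume times - lag), trimmed to the regressor
# support. Returns per lag: the retained volume indices and the samples.
shifted_regressor_samples <- function(regressor, times_s, lags) {
  t0 <- regressor$times_s[1]
  t1 <- regressor$times_s[length(regressor$times_s)]
  dt <- 1 / regressor$fs_hz
  lapply(lags, function(l) {
    tq <- times_s - l
    keep <- which(tq >= t0 & tq <= t1)
    g <- interp_uniform(regressor$values, t0, dt, tq[keep])
    list(idx = keep, g = g, n = length(keep))
  })
}

#' Lagged Pearson correlation of one voxel timeseries with the regressor
#'
#' For each lag `l` (s), computes the Pearson correlation between
#' `voxel_ts(t)` and `regressor(t - l)`, the regressor linearly interpolated
#' from its 50 Hz grid onto the shifted volume times. Negative lags mean the
#' fMRI signal leads the recorded trace, which absorbs the gas-analyser
#' transport delay (~15 s). Only overlapping samples are used (no zero
#' padding); the overlap count is recorded per lag, and lags with fewer than
#' `min_overlap` samples are marked unusable.
#'
#' @param voxel_ts numeric voxel timeseries.
#' @param times_s acquisition times of the samples (s).
#' @param regressor a `petco2_regressor` (or list with `times_s`, `values`,
#'   `fs_hz`).
#' @param lags lag grid (s); default -30 to 0 in 0.5 s steps.
#' @param min_overlap minimum usable overlap.
#' @return data.frame(`lag_s`, `r`, `n`, `usable`).
#' @export
lagged_correlation <- function(voxel_ts, times_s, regressor,
                               lags = default_lags(), min_overlap = 10) {
  sh <- shifted_regressor_samples(regressor, times_s, lags)
  r <- vapply(sh, function(s) {
    if (s$n < max(3, min_overlap)) return(NA_real_)
    x <- voxel_ts[s$idx]
    if (stats::sd(x) == 0 || stats::sd(s$g) == 0) return(NA_real_)
    stats::cor(x, s$g)
  }, numeric(1))
  n <- vapply(sh, `[[`, integer(1), "n")
  data.frame(lag_s = lags, r = r, n = n,
             usable = n >= min_overlap & is.finite(r))
}

# Correlation of every voxel column of X (time x voxel) with one regressor
# vector per lag. Returns list(R = lag x voxel, N = overlap per lag).
lag_correlation_matrix <- function(X, times_s, regressor, lags, min_overlap) {
  sh <- shifted_regressor_samples(regressor, times_s, lags)
  nlag <- length(lags)
  R <- matrix(NA_real_, nlag, ncol(X))
  N <- vapply(sh, `[[`, integer(1), "n")
  # Cache centred/normalized X per distinct overlap window.
  keys <- vapply(sh, function(s) paste(range(s$idx), collapse = ":"), character(1))
  keys[N == 0] <- NA
  for (key in unique(keys[!is.na(keys)])) {
    which_lags <- which(keys == key & N >= max(3, min_overlap))
    if (!length(which_lags)) next
    idx <- sh[[which_lags[1]]]$idx
    Xs <- X[idx, , drop = FALSE]
    Xc <- sweep(Xs, 2, colMeans(Xs))
    sx <- sqrt(colSums(Xc^2))
    sx[sx == 0] <- NA
    for (li in which_lags) {
      g <- sh[[li]]$g
      gc <- g - mean(g)
      sg <- sqrt(sum(gc^2))
      if (!is.finite(sg) || sg == 0) next
      R[li, ] <- as.vector(crossprod(Xc, gc)) / (sx * sg)
    }
  }
  list(R = R, N = N)
}

# Peak lag per voxel with midpoint tie-breaking: among equal maxima, prefer
# the lag closest to the centre of the tested range.
peak_lag_index <- function(R, lags) {
  mid <- (lags[1] + lags[length(lags)]) / 2
  pen <- 1e-12 * abs(lags - mid)
  apply(R - pen, 2, function(col) {
    if (all(is.na(col))) NA_integer_ else which.max(col)
  })
}

#' Voxelwise peak-correlation map
#'
#' Runs the lagged correlation in every in-mask voxel of a conditioned run:
#' `rmax` is the maximum correlation over the usable lags, the latency is the
#' lag at the peak (ties broken toward the range midpoint), and
#' `zmax = atanh(rmax) * sqrt(N - 3)` with `N` the number of overlapping time
#' points at the peak lag (so the variance adjustment tracks the lag-dependent
#' overlap). Voxels whose peak sits at either extreme of the tested lag range
#' are marked invalid (not a local maximum), as are voxels with insufficient
#' overlap or undefined correlations.
#'
#' @param run a conditioned `fmri_run` (ADC series use pair midpoints as
#'   sample times automatically via `volume_times_s`).
#' @param regressor a `petco2_regressor`.
#' @param mask logical 3D array (default the run's brain mask).
#' @param lags lag grid (s).
#' @param min_overlap minimum overlap per lag.
#' @param keep_profiles keep the per-voxel r(lag) curves (needed by
#'   [correlation_profile()]).
#' @param fixed_n use the full series length for every voxel's `N` instead of
#'   the overlap at the peak lag.
#' @return class `xcorr_map`: 3D arrays `rmax`, `latency_s`, `zmax`,
#'   `n_overlap`, logical `valid`, plus `lags`, `mask`, `contrast`, and
#'   optionally `per_lag_r` (lags x in-mask voxels).
#' @export
xcorr_map <- function(run, regressor, mask = NULL, lags = default_lags(),
                      min_overlap = 10, keep_profiles = FALSE, fixed_n = FALSE) {
  if (is.null(mask)) mask <- run$masks$brain
  if (is.null(mask) || !any(mask)) stop("empty mask", call. = FALSE)
  d <- dim(run$data)[1:3]
  X <- run_matrix(run, mask)
  lc <- lag_correlation_matrix(X, run$volume_times_s, regressor, lags, min_overlap)
  pk <- peak_lag_index(lc$R, lags)
  nv <- ncol(lc$R)
  rmax <- latency <- rep(NA_real_, nv)
  novl <- rep(NA_integer_, nv)
  ok <- !is.na(pk)
  rmax[ok] <- lc$R[cbind(pk[ok], which(ok))]
  latency[ok] <- lags[pk[ok]]
  novl[ok] <- if (fixed_n) nrow(X) else lc$N[pk[ok]]
  valid <- ok & is.finite(rmax) & novl >= min_overlap &
    latency > lags[1] & latency < lags[length(lags)]
  z <- atanh(pmin(pmax(rmax, -1 + 1e-12), 1 - 1e-12)) * sqrt(pmax(novl - 3, 0))

  to_map <- function(v, init = NA_real_) {
    m <- array(init, d); m[mask] <- v; m
  }
  out <- structure(list(
    rmax = to_map(rmax), latency_s = to_map(latency), zmax = to_map(z),
    n_overlap = to_map(as.numeric(novl)),
    valid = { m <- array(FALSE, d); m[mask] <- valid; m },
    lags = lags, mask = mask, contrast = run$contrast,
    latency_shift_s = 0
  ), class = "xcorr_map")
  if (keep_profiles) out$per_lag_r <- lc$R
  out
}

#' @export
print.xcorr_map <- function(x, ...) {
  cat(sprintf("<xcorr_map> %s: %d mask voxels, %d valid; lags [%g, %g] s\n",
              x$contrast %||% "?", sum(x$mask), sum(x$valid),
              x$lags[1], x$lags[length(x$lags)]))
  invisible(x)
}

#' Normalize latencies to the grey-matter median
#'
#' Shifts every voxel's latency by the median latency over valid grey-matter
#' voxels, so maps are comparable across subjects; the applied shift is
#' recorded in `latency_shift_s`.
#'
#' @param map an `xcorr_map`.
#' @param gm_mask logical 3D grey-matter mask.
#' @return the map with normalized `latency_s` and the shift recorded.
#' @export
normalize_latency <- function(map, gm_mask) {
  sel <- map$valid & gm_mask
  if (!any(sel)) stop("no valid grey-matter voxels", call. = FALSE)
  shift <- stats::median(map$latency_s[sel])
  map$latency_s <- map$latency_s - shift
  map$latency_shift_s <- map$latency_shift_s + shift
  map
}

#' Mean correlation profile over significant voxels
#'
#' Averages the per-voxel r(lag) curves across voxels flagged in `sig_mask`,
#' with the lag axis shifted by the grey-matter median latency so profiles
#' align across subjects. The map must have been computed with
#' `keep_profiles = TRUE`.
#'
#' @param map an `xcorr_map` with `per_lag_r`.
#' @param sig_mask logical 3D array of voxels to average (e.g.
#'   `map$valid & map$zmax > zthresh`).
#' @param gm_mask grey-matter mask used for the latency shift; if `NULL` the
#'   map's recorded `latency_shift_s` is used.
#' @return data.frame(`lag_s` (shifted), `mean_r`, `n_voxels`); zero rows
#'   (with a warning) when no voxel is significant.
#' @export
correlation_profile <- function(map, sig_mask, gm_mask = NULL) {
  if (is.null(map$per_lag_r))
    stop("map was computed without keep_profiles = TRUE", call. = FALSE)
  shift <- if (!is.null(gm_mask)) {
    sel <- map$valid & gm_mask
    if (!any(sel)) stop("no valid grey-matter voxels", call. = FALSE)
    stats::median(map$latency_s[sel]) + map$latency_shift_s
  } else map$latency_shift_s
  pick <- sig_mask[map$mask]
  if (!any(pick)) {
    warning("no significant voxels; returning an empty profile")
    return(data.frame(lag_s = numeric(0), mean_r = numeric(0),
                      n_voxels = integer(0)))
  }
  prof <- rowMeans(map$per_lag_r[, pick, drop = FALSE], na.rm = TRUE)
  data.frame(lag_s = map$lags - shift, mean_r = prof, n_voxels = sum(pick))
}
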