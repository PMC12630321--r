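# Phase-randomization surrogate analysis: contrast-specific empirical null
# distributions of zmax and the derived significance thresholds.

#' Phase-randomize a series
#'
#' Fourier-transform the series, draw the phases of the positive-frequency
#' coefficients uniformly (conjugate-mirrored onto the negative frequencies,
#' DC and Nyquist kept real), and invert. The surrogate preserves the
#' magnitude spectrum — hence the autocorrelation, mean and variance — while
#' destroying any phase-locked structure.
#'
#' @param x numeric series (length >= 4), or a `petco2_regressor`.
#' @param seed integer seed.
#' @return surrogate of the same type and length.
#' @export
phase_randomize <- function(x, seed = NULL) {
  if (inherits(x, "petco2_regressor")) {
    x$values <- phase_randomize(x$values, seed)
    return(x)
  }
  n <- length(x)
  if (n < 4) stop("series too short to phase-randomize", call. = FALSE)
  if (any(!is.finite(x))) stop("series must be finite", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  X <- stats::fft(x)
  half <- floor((n - 1) / 2)            # strictly positive, non-Nyquist bins
  ph <- stats::runif(half, 0, 2 * pi)
  idx <- 2:(half + 1)
  X[idx] <- Mod(X[idx]) * exp(1i * ph)
  X[n + 2 - idx] <- Conj(X[idx])
  if (n %% 2 == 0) X[n / 2 + 1] <- Mod(X[n / 2 + 1]) * sign(Re(X[n / 2 + 1]) + (Re(X[n / 2 + 1]) == 0))
  Re(stats::fft(X, inverse = TRUE)) / n
}

# m phase-randomized copies of x as an n x m matrix (vectorized FFT).
phase_randomize_matrix <- function(x, m) {
  n <- length(x)
  X <- stats::fft(x)
  half <- floor((n - 1) / 2)
  idx <- 2:(half + 1)
  C <- matrix(rep(X, m), n, m)
  ph <- matrix(stats::runif(half * m, 0, 2 * pi), half, m)
  C[idx, ] <- Mod(X[idx]) * exp(1i * ph)
  C[n + 2 - idx, ] <- Conj(C[idx, , drop = FALSE])
  Re(stats::mvfft(C, inverse = TRUE)) / n
}

# zmax for paired (surrogate series j, voxel series j) lagged correlations.
# G50: grid-sampled series (n50 x m) on (t0, fs); X: time x m voxel matrix
# sampled at times_s. Max over the tested lags; N = overlap at the peak lag.
# Pairs whose peak falls at a lag-range extreme are flagged `boundary` so the
# null can apply the same exclusion rule as the voxelwise maps it calibrates.
pairwise_lag_zmax <- function(G50, t0, fs, X, times_s, lags, min_overlap = 10) {
  n50 <- nrow(G50)
  t1 <- t0 + (n50 - 1) / fs
  m <- ncol(X)
  R <- matrix(NA_real_, length(lags), m)
  Nl <- integer(length(lags))
  win <- lapply(lags, function(l) {
    tq <- times_s - l
    keep <- which(tq >= t0 & tq <= t1)
    pos <- (tq[keep] - t0) * fs + 1
    i0 <- floor(pos); i0[i0 == n50] <- n50 - 1L
    list(idx = keep, i0 = i0, w = pos - i0)
  })
  keys <- vapply(win, function(s) paste(range(s$idx), collapse = ":"), character(1))
  for (key in unique(keys[vapply(win, function(s) length(s$idx), integer(1)) > 0])) {
    lset <- which(keys == key)
    idx <- win[[lset[1]]]$idx
    if (length(idx) < max(3, min_overlap)) next
    Xs <- X[idx, , drop = FALSE]
    Xc <- sweep(Xs, 2, colMeans(Xs))
    sx <- sqrt(colSums(Xc^2)); sx[sx == 0] <- NA
    for (li in lset) {
      Nl[li] <- length(idx)
      i0 <- win[[li]]$i0; w <- win[[li]]$w
      G <- G50[i0, , drop = FALSE] * (1 - w) + G50[i0 + 1L, , drop = FALSE] * w
      Gc <- sweep(G, 2, colMeans(G))
      sg <- sqrt(colSums(Gc^2)); sg[sg == 0] <- NA
      R[li, ] <- colSums(Xc * Gc) / (sx * sg)
    }
  }
  pk <- peak_lag_index(R, lags)
  out <- rep(NA_real_, m)
  ok <- !is.na(pk)
  rmax <- R[cbind(pk[ok], which(ok))]
  out[ok] <- atanh(pmin(pmax(rmax, -1 + 1e-12), 1 - 1e-12)) *
    sqrt(pmax(Nl[pk[ok]] - 3, 0))
  boundary <- rep(NA, m)
  boundary[ok] <- pk[ok] == 1L | pk[ok] == length(lags)
  list(zmax = out, boundary = boundary)
}

#' Build the surrogate null distribution of zmax
#'
#' Leave-one-out across subjects: taking each subject in turn as reference,
#' `n_surrogates` phase-randomized copies of its pETCO2 regressor are
#' cross-correlated (full lag grid, peak-over-lags, Fisher z) against voxels
#' sampled without replacement from the brain masks of every *other* subject
#' (per-donor draws of `n_voxels`, surrogate j paired with voxel j; set
#' `pool_donors = TRUE` to draw one pooled batch across donors per
#' reference). All zmax values are pooled into one empirical null.
#'
#' @param cohort list of subjects, each a list with `regressor`
#'   (a `petco2_regressor`) and `run` (a conditioned `fmri_run`).
#' @param n_surrogates surrogates per reference subject.
#' @param n_voxels voxels sampled per donor.
#' @param seed master seed; the (reference, donor) pair seed is
#'   `seed + 1000 * ref + donor` and all pair seeds are recorded.
#' @param lags lag grid (s).
#' @param min_overlap minimum overlap per lag.
#' @return class `null_distribution`: `samples`, `contrast`, `n_surrogates`,
#'   `n_voxels`, `seeds`, `threshold_p05`.
#' @export
build_null <- function(cohort, n_surrogates = 5000, n_voxels = 5000,
                       seed = 1, lags = default_lags(), min_overlap = 10,
                       pool_donors = FALSE) {
  S <- length(cohort)
  if (S < 2) stop("surrogate null requires at least 2 subjects", call. = FALSE)
  samples <- numeric(0)
  seeds <- list()
  n_pairs_total <- 0L
  for (s in seq_len(S)) {
    reg <- cohort[[s]]$regressor
    donors <- setdiff(seq_len(S), s)
    if (pool_donors) donors <- list(donors) else donors <- as.list(donors)
    for (dset in donors) {
      pair_seed <- seed + 1000L * s + dset[1]
      set.seed(pair_seed)
      seeds[[length(seeds) + 1L]] <- c(ref = s, donor = dset[1], seed = pair_seed)
      Xall <- do.call(cbind, lapply(dset, function(d) {
        run <- cohort[[d]]$run
        mask_idx <- which(as.vector(run$masks$brain))
        vox <- sample(mask_idx, min(n_voxels, length(mask_idx)))
        run_matrix(run)[, vox, drop = FALSE]
      }))
      m <- min(n_surrogates, ncol(Xall))
      G <- phase_randomize_matrix(reg$values, m)
      times <- cohort[[dset[1]]]$run$volume_times_s
      z <- pairwise_lag_zmax(G, reg$times_s[1], reg$fs_hz,
                             Xall[, seq_len(m), drop = FALSE], times, lags,
                             min_overlap)
      keep <- is.finite(z$zmax) & !z$boundary
      n_pairs_total <- n_pairs_total + m
      samples <- c(samples, z$zmax[keep])
    }
  }
  structure(list(samples = samples,
                 contrast = cohort[[1]]$run$contrast,
                 n_pairs_total = n_pairs_total,
                 n_boundary_excluded = n_pairs_total - length(samples),
                 n_surrogates = n_surrogates, n_voxels = n_voxels,
                 seeds = do.call(rbind, seeds),
                 threshold_p05 = stats::quantile(samples, 0.95, names = FALSE)),
            class = "null_distribution")
}

#' One-tailed significance threshold from a null distribution
#'
#' Empirical `(1 - p)` quantile (order statistic with linear interpolation)
#' of the pooled surrogate zmax samples.
#'
#' @param null a `null_distribution` (or numeric sample vector).
#' @param p one-tailed significance level.
#' @return the z threshold.
#' @export
significance_threshold <- function(null, p = 0.05) {
  samples <- if (inherits(null, "null_distribution")) null$samples else null
  if (length(samples) < 100)
    stop(sprintf("need at least 100 null samples (got %d)", length(samples)),
         call. = FALSE)
  stats::quantile(samples, 1 - p, names = FALSE)
}
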