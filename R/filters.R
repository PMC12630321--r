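# Internal signal-processing primitives shared by the physio and conditioning
# stages: zero-phase Butterworth filtering (vector and time-by-voxel matrix
# forms) and fast linear interpolation from a uniform grid.

# Design a Butterworth filter; `cutoff_hz` must lie strictly below Nyquist.
butter_coefs <- function(order, cutoff_hz, fs_hz, type = c("low", "high")) {
  type <- match.arg(type)
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0)
    stop("cutoff_hz must be positive", call. = FALSE)
  if (cutoff_hz >= fs_hz / 2)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, fs_hz / 2), call. = FALSE)
  bf <- signal::butter(order, W = cutoff_hz / (fs_hz / 2), type = type)
  list(b = bf$b, a = bf$a)
}

# Odd (anti-symmetric) reflection padding, as used by standard filtfilt
# implementations, to suppress startup transients at the series edges.
pad_reflect <- function(n, npad) {
  npad <- min(npad, n - 1L)
  list(head = seq(npad + 1L, 2L, by = -1L),
       tail = seq(n - 1L, n - npad, by = -1L),
       npad = npad)
}

# IIR difference equation applied down the rows of a time-by-series matrix.
iir_filter_mat <- function(b, a, X) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b); na <- length(a)
  n <- nrow(X); m <- ncol(X)
  Y <- matrix(0, n, m)
  for (t in seq_len(n)) {
    acc <- b[1] * X[t, ]
    if (nb > 1 && t > 1) for (j in 2:min(nb, t)) acc <- acc + b[j] * X[t - j + 1L, ]
    if (na > 1 && t > 1) for (j in 2:min(na, t)) acc <- acc - a[j] * Y[t - j + 1L, ]
    Y[t, ] <- acc
  }
  Y
}

# Zero-phase (forward-backward) filtering of a matrix (time x series) with
# reflective padding of roughly one impulse-response length. The series mean
# is removed before filtering and restored through the filter's squared DC
# gain, so constant inputs pass (low-pass) or vanish (high-pass) exactly.
filtfilt_mat <- function(b, a, X, npad = NULL) {
  n <- nrow(X)
  if (is.null(npad)) npad <- 3L * (max(length(a), length(b)) - 1L) * 10L
  g2 <- (sum(b) / sum(a))^2
  mu <- colMeans(X)
  X <- sweep(X, 2, mu)
  p <- pad_reflect(n, npad)
  Xp <- rbind(2 * X[rep(1L, p$npad), , drop = FALSE] - X[p$head, , drop = FALSE],
              X,
              2 * X[rep(n, p$npad), , drop = FALSE] - X[p$tail, , drop = FALSE])
  Y <- iir_filter_mat(b, a, Xp)
  Y <- iir_filter_mat(b, a, Y[nrow(Y):1L, , drop = FALSE])
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  sweep(Y[(p$npad + 1L):(p$npad + n), , drop = FALSE], 2, g2 * mu, "+")
}

# Vector form; uses signal::filter (C speed) for long physiological traces.
filtfilt_vec <- function(b, a, x, npad = NULL) {
  n <- length(x)
  if (is.null(npad)) npad <- 3L * (max(length(a), length(b)) - 1L) * 10L
  g2 <- (sum(b) / sum(a))^2
  mu <- mean(x)
  x <- x - mu
  p <- pad_reflect(n, npad)
  xp <- c(2 * x[1] - x[p$head], x, 2 * x[n] - x[p$tail])
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(p$npad + 1L):(p$npad + n)] + g2 * mu
}

# Linear interpolation of `values` sampled uniformly (t0, dt) at query times.
# Queries outside the grid return NA (the caller trims the overlap).
interp_uniform <- function(values, t0, dt, tq) {
  n <- length(values)
  pos <- (tq - t0) / dt + 1
  out <- rep(NA_real_, length(tq))
  ok <- pos >= 1 & pos <= n
  i0 <- floor(pos[ok])
  i0[i0 == n] <- n - 1L
  w <- pos[ok] - i0
  out[ok] <- values[i0] * (1 - w) + values[i0 + 1L] * w
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
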