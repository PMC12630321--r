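# Per-run signal conditioning, motion QC, the noise-amplification control,
# SNR metrics, and the temporal downsampling control.

# Apply a kernel matrix along one axis of a 4D array.
conv_axis <- function(A, K, axis) {
  d <- dim(A)
  perm <- c(axis, setdiff(seq_along(d), axis))
  B <- aperm(A, perm)
  dim(B) <- c(d[axis], prod(d[-axis]))
  B <- K %*% B
  dim(B) <- d[perm]
  aperm(B, order(perm))
}

gauss_kernel_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  g <- stats::dnorm(-r:r, sd = sigma_vox)
  g <- g / sum(g)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- g[ok]
  }
  K
}

#' Spatial Gaussian smoothing
#'
#' Per-volume 3D Gaussian smoothing with a kernel of the stated full width at
#' half maximum; `sigma_voxels = fwhm / (2 sqrt(2 log 2) * voxel_size)` per
#' axis (2.3548 voxels per FWHM). The whole volume is smoothed (separable
#' normalized kernel, zero padding) with no in-mask renormalization; interior
#' intensity is conserved, values near the grid edge lose a little mass.
#'
#' @param run an `fmri_run`.
#' @param fwhm_mm kernel FWHM (mm).
#' @return the smoothed run.
#' @export
smooth_spatial <- function(run, fwhm_mm = 4) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive", call. = FALSE)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / run$voxel_size_mm
  d <- dim(run$data)
  A <- run$data
  for (ax in 1:3) A <- conv_axis(A, gauss_kernel_matrix(d[ax], sigma), ax)
  run$data <- A
  run
}

#' Temporal high-pass filtering
#'
#' Per-voxel zero-phase Butterworth high-pass (default 0.01 Hz, 4th order) at
#' the run's effective sampling rate `1 / TR`. Edges are handled with odd
#' reflective padding to suppress startup transients on short runs.
#'
#' @param run an `fmri_run` (works on ADC series too, where the effective
#'   sampling interval is twice the acquisition TR).
#' @param cutoff_hz high-pass cutoff (Hz).
#' @param order filter order.
#' @return the filtered run.
#' @export
highpass_temporal <- function(run, cutoff_hz = 0.01, order = 4) {
  fs <- 1 / mean(diff(run$volume_times_s))
  co <- butter_coefs(order, cutoff_hz, fs, "high")
  d <- dim(run$data)
  X <- t(matrix(run$data, prod(d[1:3]), d[4]))        # time x voxel
  if (d[4] <= 3 * order)
    stop("run is shorter than the filter warm-up", call. = FALSE)
  Y <- filtfilt_mat(co$b, co$a, X, npad = d[4] - 1L)
  run$data <- array(t(Y), dim = d)
  run
}

#' Framewise displacement and absolute displacement
#'
#' Power-style framewise displacement: the sum of absolute volume-to-volume
#' differences of the three translations plus `head_radius_mm` times the sum
#' of absolute rotation differences. Absolute displacement uses the same norm
#' against the first volume.
#'
#' @param motion a `motion_trace` (n x 6 matrix: translations mm, rotations rad).
#' @param head_radius_mm rotation-to-arc conversion radius (default 50 mm).
#' @return list(`fd_mm` (length n, first element 0), `mean_fd_mm`,
#'   `abs_displacement_mm`, `max_abs_displacement_mm`).
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  M <- unclass(motion)
  if (nrow(M) < 2) stop("need at least 2 volumes", call. = FALSE)
  dM <- abs(diff(M))
  fd <- c(0, rowSums(dM[, 1:3, drop = FALSE]) +
             head_radius_mm * rowSums(dM[, 4:6, drop = FALSE]))
  ref <- abs(sweep(M, 2, M[1, ]))
  absd <- rowSums(ref[, 1:3, drop = FALSE]) +
          head_radius_mm * rowSums(ref[, 4:6, drop = FALSE])
  list(fd_mm = fd, mean_fd_mm = mean(fd[-1]),
       abs_displacement_mm = absd, max_abs_displacement_mm = max(absd))
}

#' Motion quality-control gate
#'
#' A run is rejected iff its maximum absolute displacement exceeds one voxel
#' or its mean framewise displacement exceeds `fd_threshold_mm` (strict
#' inequalities); reasons are recorded. Pure function of its inputs.
#'
#' @param motion a `motion_trace`, or a precomputed
#'   [framewise_displacement()] result.
#' @param voxel_size_mm voxel size defining the one-voxel rule (mm).
#' @param fd_threshold_mm mean-FD rejection threshold (default 0.2 mm).
#' @param head_radius_mm passed to [framewise_displacement()].
#' @return class `run_qc`: list(`max_abs_displacement_mm`, `mean_fd_mm`,
#'   `voxel_size_mm`, `accepted`, `reasons`).
#' @export
qc_gate <- function(motion, voxel_size_mm, fd_threshold_mm = 0.2,
                    head_radius_mm = 50) {
  m <- if (inherits(motion, "motion_trace") || is.matrix(motion))
    framewise_displacement(motion, head_radius_mm) else motion
  reasons <- character(0)
  if (m$max_abs_displacement_mm > voxel_size_mm)
    reasons <- c(reasons, sprintf(
      "max absolute displacement %.3g mm exceeds one voxel (%.3g mm)",
      m$max_abs_displacement_mm, voxel_size_mm))
  if (m$mean_fd_mm > fd_threshold_mm)
    reasons <- c(reasons, sprintf(
      "mean framewise displacement %.3g mm exceeds %.3g mm",
      m$mean_fd_mm, fd_threshold_mm))
  structure(list(max_abs_displacement_mm = m$max_abs_displacement_mm,
                 mean_fd_mm = m$mean_fd_mm, voxel_size_mm = voxel_size_mm,
                 accepted = length(reasons) == 0, reasons = reasons),
            class = "run_qc")
}

#' Noise amplification by permuted-residual injection
#'
#' `noised = denoised + k * residuals[, , , perm]`, where `perm` is a single
#' seeded permutation of the volume indices shared by all voxels (preserving
#' the spatial covariance of the noise while breaking its temporal alignment
#' with the task). Set `per_voxel = TRUE` for independent per-voxel
#' permutations, or `permutation` to force one (e.g. the identity).
#'
#' @param denoised,residuals `fmri_run`s or 4D arrays of the same shape.
#' @param k noise amplification factor.
#' @param seed integer seed.
#' @param permutation optional explicit permutation of volume indices.
#' @param per_voxel permute each voxel's residuals independently.
#' @return object of the same type as `denoised`, with attribute
#'   `permutation` (volume-wise mode).
#' @export
amplify_noise <- function(denoised, residuals, k, seed = NULL,
                          permutation = NULL, per_voxel = FALSE) {
  dn <- if (inherits(denoised, "fmri_run")) denoised$data else denoised
  rs <- if (inherits(residuals, "fmri_run")) residuals$data else residuals
  if (!identical(dim(dn), dim(rs)))
    stop("denoised and residuals must have the same shape", call. = FALSE)
  nt <- dim(dn)[4]
  if (!is.null(seed)) set.seed(seed)
  if (per_voxel) {
    nv <- prod(dim(rs)[1:3])
    R <- matrix(rs, nv, nt)
    R <- t(apply(R, 1, sample))
    out <- dn + k * array(R, dim(dn))
    perm <- NULL
  } else {
    perm <- permutation %||% sample.int(nt)
    out <- dn + k * rs[, , , perm, drop = FALSE]
  }
  if (inherits(denoised, "fmri_run")) {
    denoised$data <- out
    attr(denoised, "permutation") <- perm
    denoised
  } else structure(out, permutation = perm)
}

#' Image SNR from a denoised/residual split
#'
#' Mean denoised signal within the mask divided by the standard deviation of
#' the removed (residual) components within the mask.
#'
#' @param denoised,residuals 4D arrays or `fmri_run`s on the same grid.
#' @param mask logical 3D array.
#' @return scalar SNR.
#' @export
image_snr <- function(denoised, residuals, mask) {
  dn <- if (inherits(denoised, "fmri_run")) denoised$data else denoised
  rs <- if (inherits(residuals, "fmri_run")) residuals$data else residuals
  nt <- dim(dn)[4]
  m4 <- array(mask, dim(dn))
  s <- stats::sd(rs[m4])
  if (!is.finite(s) || s == 0)
    stop("residual standard deviation is zero; SNR undefined", call. = FALSE)
  mean(dn[m4]) / s
}

#' Temporal SNR map
#'
#' Per-voxel temporal mean divided by temporal SD over a baseline window
#' (volume indices), so the estimate is not impacted by task fluctuations.
#' Voxels with zero temporal SD are returned as `NA` and flagged.
#'
#' @param run an `fmri_run`.
#' @param window integer volume indices (default the first 18 s worth).
#' @return 3D tSNR map with attribute `flagged` (zero-SD voxels).
#' @export
temporal_snr <- function(run, window = NULL) {
  nt <- dim(run$data)[4]
  if (is.null(window)) window <- seq_len(max(2L, min(nt, round(18 / run$TR_s))))
  if (any(window < 1 | window > nt)) stop("window outside the run", call. = FALSE)
  d <- dim(run$data)
  X <- matrix(run$data, prod(d[1:3]), nt)[, window, drop = FALSE]
  mu <- rowMeans(X)
  sd_ <- sqrt(rowSums((X - mu)^2) / (length(window) - 1))
  out <- mu / sd_
  flagged <- sd_ == 0
  out[flagged] <- NA_real_
  map <- array(out, d[1:3])
  attr(map, "flagged") <- array(flagged, d[1:3])
  map
}

#' Downsample a run by keeping every other time point
#'
#' Retains volumes 1, 3, 5, ... (even indices when counting from zero),
#' doubles the TR, and keeps the original acquisition times of the retained
#' volumes. Used as the sampling-rate control for BOLD-vs-diffusion
#' comparisons (the diffusion series have half the BOLD sampling rate).
#'
#' @param run an `fmri_run` with at least 4 volumes.
#' @return the downsampled run.
#' @export
downsample_keep_every_other <- function(run) {
  nt <- dim(run$data)[4]
  if (nt < 4) stop("need at least 4 volumes", call. = FALSE)
  idx <- seq(1, nt, by = 2)
  run$data <- run$data[, , , idx, drop = FALSE]
  run$volume_times_s <- run$volume_times_s[idx]
  if (!is.null(run$b_schedule)) run$b_schedule <- run$b_schedule[idx]
  run$TR_s <- run$TR_s * 2
  run
}
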