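mk_run <- function(A, TR_s = 1, voxel_size_mm = 2.8) {
  fmri_run(A, TR_s = TR_s, contrast = "BOLD",
           masks = list(brain = array(TRUE, dim(A)[1:3])),
           voxel_size_mm = voxel_size_mm)
}

test_that("spatial smoothing: conservation, kernel width, uniform invariance", {
  dims <- c(15, 15, 9)
  A <- array(0, c(dims, 1)); A[8, 8, 5, 1] <- 1
  sm <- smooth_spatial(mk_run(A), fwhm_mm = 4)
  expect_lt(abs(sum(sm$data) - 1), 1e-6)
  # kernel uses sigma = fwhm / (2 sqrt(2 log 2)) / voxel_size = 0.6067 voxels
  sigma <- 4 / (2 * sqrt(2 * log(2))) / 2.8
  expect_equal(round(sigma, 4), 0.6067)
  prof <- apply(sm$data[, , , 1], 1, sum)
  g <- stats::dnorm(-7:7, sd = sigma)        # offsets -3..3 sit at indices 5:11
  expect_equal(prof[5:11] / max(prof), g[5:11] / max(g), tolerance = 1e-9)
  U <- array(7, c(dims, 2))
  smu <- smooth_spatial(mk_run(U))
  expect_lt(max(abs(smu$data[5:11, 5:11, 4:6, ] - 7)), 1e-9)  # beyond kernel radius
  expect_error(smooth_spatial(mk_run(U), fwhm_mm = 0), "positive")
})

test_that("temporal high-pass: DC removed, band edges, linearity", {
  t <- (1:1000) - 0.5
  mkA <- function(v) array(rep(v, each = 4), c(2, 2, 1, length(v)))
  hp <- function(v, ...) highpass_temporal(mk_run(mkA(v)), ...)$data[1, 1, 1, ]
  expect_lt(max(abs(hp(rep(5, 1000)))), 1e-8)
  y1 <- hp(sin(2 * pi * 0.05 * t))
  expect_gt(max(abs(y1[200:800])), 0.95)
  y2 <- hp(sin(2 * pi * 0.002 * t))
  expect_lt(max(abs(y2[200:800])), 0.10)
  # linearity of the whole conditioning chain
  a <- stats::rnorm(100); b <- stats::rnorm(100)
  lin <- function(op) {
    xa <- op(mk_run(mkA(a)))$data; xb <- op(mk_run(mkA(b)))$data
    xab <- op(mk_run(mkA(2 * a - 3 * b)))$data
    max(abs(xab - (2 * xa - 3 * xb)))
  }
  expect_lt(lin(function(r) highpass_temporal(r)), 1e-8)
  expect_lt(lin(function(r) smooth_spatial(r)), 1e-8)
  expect_error(highpass_temporal(mk_run(mkA(rep(1, 1000))), cutoff_hz = 0.6),
               "Nyquist")
})

test_that("framewise displacement arithmetic", {
  M <- matrix(0, 3, 6)
  M[2, 1:3] <- 0.1                       # translation step of (0.1, 0.1, 0.1)
  fd <- framewise_displacement(structure(M, class = c("motion_trace", "matrix")))
  expect_equal(fd$fd_mm[2], 0.3)
  M2 <- matrix(0, 2, 6); M2[2, 4] <- 0.002
  fd2 <- framewise_displacement(structure(M2, class = c("motion_trace", "matrix")))
  expect_equal(fd2$fd_mm[2], 0.1)
  expect_equal(framewise_displacement(generate_motion(10))$fd_mm, rep(0, 10))
})

test_that("QC gate applies the one-voxel and 0.2 mm rules strictly", {
  qc1 <- qc_gate(list(max_abs_displacement_mm = 3.0, mean_fd_mm = 0.1),
                 voxel_size_mm = 2.8)
  expect_false(qc1$accepted)
  expect_match(qc1$reasons[1], "one voxel")
  qc2 <- qc_gate(list(max_abs_displacement_mm = 1.0, mean_fd_mm = 0.2),
                 voxel_size_mm = 2.8)
  expect_true(qc2$accepted)          # threshold itself is accepted
  qc3 <- qc_gate(list(max_abs_displacement_mm = 1.0, mean_fd_mm = 0.25),
                 voxel_size_mm = 2.8)
  expect_false(qc3$accepted)
  # pure function: same inputs, same decision
  expect_identical(qc3, qc_gate(list(max_abs_displacement_mm = 1.0,
                                     mean_fd_mm = 0.25), voxel_size_mm = 2.8))
})

test_that("noise amplification: identity, variance scaling, mean preservation", {
  dims <- c(10, 10, 10, 100)
  set.seed(8)
  den <- array(100, dims)
  res <- array(stats::rnorm(prod(dims), 0, 5), dims)
  expect_equal(amplify_noise(den, array(0, dims), k = 8, seed = 1), den,
               ignore_attr = TRUE)
  exact <- amplify_noise(den, res, k = 1, permutation = seq_len(100))
  expect_equal(exact, den + res, ignore_attr = TRUE)
  for (k in c(4, 16)) {
    noised <- amplify_noise(den, res, k = k, seed = k)
    expect_rel_equal(stats::var(as.vector(noised - den)),
                     k^2 * stats::var(as.vector(res)), 0.01)
  }
  # volume-wise permutation: one permutation shared by all voxels
  n1 <- amplify_noise(den, res, k = 2, seed = 3)
  perm <- attr(n1, "permutation")
  expect_equal(n1, den + 2 * res[, , , perm], ignore_attr = TRUE)
  expect_error(amplify_noise(den, res[, , , 1:50], k = 2), "same shape")
})

test_that("image SNR and temporal SNR recover generator truth", {
  expect_equal(image_snr(array(100, c(4, 4, 2, 5)),
                         array(rep(c(-10, 10), 80), c(4, 4, 2, 5)),
                         array(TRUE, c(4, 4, 2))),
               100 / stats::sd(rep(c(-10, 10), 80)))
  dims <- c(12, 12, 8); masks <- make_masks(dims)
  gt <- make_ground_truth(dims, masks$GM, masks$WM, amp_gm = 0, amp_wm = 0,
                          noise_sigma = 25, S0 = 500, TE_s = 0)
  drv <- make_vascular_driver(bh_trace())
  run <- generate_fmri_run("BOLD", gt, drv, n_vols = 30,
                           store_noiseless = TRUE, seed = 77)
  res <- run$data - run$truth$noiseless
  snr <- image_snr(run$truth$noiseless, res, masks$brain)
  expect_gt(prod(dims) * 30, 1e4)
  expect_rel_equal(snr, 20, 0.02)
  # residual scaling divides the SNR exactly
  expect_equal(image_snr(run$truth$noiseless, 2 * res, masks$brain), snr / 2)
  tsnr <- temporal_snr(run, window = 1:18)
  expect_rel_equal(mean(tsnr), 20, 0.05)
  # constant offset raises tSNR, temporal SD unchanged
  run2 <- run; run2$data <- run2$data + 100
  expect_gt(mean(temporal_snr(run2, window = 1:18)), mean(tsnr))
  expect_error(image_snr(run$data, array(0, dim(run$data)), masks$brain),
               "zero")
})

test_that("downsampling keeps every other volume and doubles TR", {
  A <- array(stats::rnorm(2 * 2 * 1 * 192), c(2, 2, 1, 192))
  run <- mk_run(A, TR_s = 1)
  d1 <- downsample_keep_every_other(run)
  expect_equal(dim(d1$data)[4], 96)
  expect_equal(d1$TR_s, 2)
  expect_equal(d1$volume_times_s, run$volume_times_s[seq(1, 192, 2)])
  expect_identical(d1$data[, , , 3], run$data[, , , 5])
  d2 <- downsample_keep_every_other(d1)
  expect_equal(dim(d2$data)[4], 48)
})
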