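# Helper: a minimal interleaved diffusion run from a time x voxel matrix.
dw_run <- function(S, TR_s = 1, b = c(0, 0, rep(c(200, 1000), (nrow(S) - 2) / 2))) {
  nv <- ncol(S)
  fmri_run(array(t(S), dim = c(nv, 1, 1, nrow(S))), TR_s = TR_s,
           contrast = "dfmri", b_schedule = b,
           masks = list(brain = array(TRUE, c(nv, 1, 1))))
}

test_that("splitting an interleaved run and re-interleaving is lossless", {
  S <- matrix(seq_len(12 * 3) + 100, 12, 3)
  run <- dw_run(S)
  sp <- split_dfmri(run)
  expect_equal(dim(sp$b200$data)[4], 5)
  expect_equal(dim(sp$b1000$data)[4], 5)
  expect_equal(sp$b200$TR_s, 2)
  expect_equal(sp$b200$volume_times_s[1], run$volume_times_s[3])
  expect_equal(sp$b1000$volume_times_s[1], run$volume_times_s[4])
  rt <- interleave_dfmri(sp$b200, sp$b1000)
  expect_identical(rt$data[, , , ], run$data[, , , 3:12])
  bad <- dw_run(S, b = c(0, 0, 200, 200, rep(c(200, 1000), 4)))
  expect_error(split_dfmri(bad), "alternating")
})

test_that("two-point ADC: log-ratio arithmetic and invalid flagging", {
  S <- matrix(0, 4, 2)
  S[, 1] <- c(500, 500, 0.85214, 0.44933)       # mono-exponential ADC 8e-4
  S[, 2] <- c(500, 500, 300, 300)               # equal pair -> ADC 0
  adc <- compute_adc_series(dw_run(S))
  expect_equal(adc$data[1, 1, 1, 1], 8.0e-4, tolerance = 1e-4)
  expect_equal(adc$data[2, 1, 1, 1], 0)
  expect_equal(adc$volume_times_s, mean(c(2.5, 3.5)))
  expect_equal(adc$TR_s, 2)
  # non-positive intensity is flagged, not clipped
  Sbad <- matrix(c(500, 500, -1, 300), 4, 1)
  adcb <- compute_adc_series(dw_run(Sbad))
  expect_true(adcb$invalid_mask[1, 1, 1, 1])
  expect_true(is.na(adcb$data[1, 1, 1, 1]))
})

test_that("per-pair multiplicative modulation cancels over many random trials", {
  set.seed(101)
  n_pairs <- 1000
  s200 <- exp(-200 * 0.8e-3) * 500
  s1000 <- exp(-1000 * 0.8e-3) * 500
  base <- matrix(c(500, 500, rep(c(s200, s1000), n_pairs)), ncol = 1)
  f <- exp(stats::rnorm(n_pairs, 0, 0.3))          # random positive factors
  mod <- base
  mod[seq(3, nrow(mod), 2), 1] <- mod[seq(3, nrow(mod), 2), 1] * f
  mod[seq(4, nrow(mod), 2), 1] <- mod[seq(4, nrow(mod), 2), 1] * f
  a0 <- compute_adc_series(dw_run(base))
  a1 <- compute_adc_series(dw_run(mod))
  expect_lt(max(abs(a1$data - a0$data)), 1e-15)
  expect_equal(unique(as.vector(a0$data)), 0.8e-3, tolerance = 1e-12)
})

test_that("ADC increases monotonically as the high-b signal decreases", {
  s_lo <- 400
  s_hi <- seq(350, 50, by = -50)
  adc <- -log(s_hi / s_lo) / 800
  expect_true(all(diff(adc) > 0))
  S <- rbind(rep(0, length(s_hi)), rep(0, length(s_hi)),
             rep(s_lo, length(s_hi)), s_hi)
  S[1:2, ] <- 500
  out <- compute_adc_series(dw_run(S))
  expect_true(all(diff(out$data[, 1, 1, 1]) > 0))
})

test_that("generator neural ADC response is recovered exactly at pair resolution", {
  dims <- c(4, 4, 2); masks <- make_masks(dims)
  tc <- list(t0 = -35, fs_hz = 50,
             values = 0.02 * sin(2 * pi * 0.02 * seq(-35, 250, by = 1 / 50)))
  gt <- make_ground_truth(dims, masks$GM, masks$WM, amp_gm = 0, amp_wm = 0,
                          noise_sigma = 0, ivim_fraction = 0,
                          neural_adc_amplitude = array(1, dims),
                          neural_adc_timecourse = tc)
  drv <- make_vascular_driver(bh_trace())
  run <- generate_fmri_run("dfmri", gt, drv, TR_s = 1, n_pairs = 90)
  adc <- compute_adc_series(run)
  a_t <- stats::approx(tc$t0 + (seq_along(tc$values) - 1) / 50, tc$values,
                       adc$volume_times_s)$y
  expected <- gt$adc_baseline * (1 + a_t)
  expect_equal(as.vector(adc$data[1, 1, 1, ]), expected, tolerance = 1e-12)
})

test_that("CSF partial-volume estimator matches direct mixture evaluation", {
  expect_equal(csf_partial_volume_effect(delta_f_csf = 0), 0)
  expect_equal(csf_partial_volume_effect(
    fractions = c(csf = 0, tissue = 1),
    diffusivities = c(3.0e-3, 0.8e-3), delta_f_csf = 0), 0)
  # two-compartment oracle computed directly in the test
  D <- c(3.0e-3, 0.8e-3)
  f0 <- c(0.10, 0.90); f1 <- c(0.094, 0.906)
  adc_of <- function(f) {
    s <- function(b) f[1] * exp(-b * D[1]) + f[2] * exp(-b * D[2])
    -log(s(1000) / s(200)) / 800
  }
  oracle <- (adc_of(f1) - adc_of(f0)) / adc_of(f0)
  got <- csf_partial_volume_effect(fractions = c(csf = 0.10, tissue = 0.90),
                                   diffusivities = D, delta_f_csf = -0.006)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_lt(oracle, 0)  # losing CSF volume lowers the measured ADC
  # relative interpretation moves 0.6% of the CSF fraction instead
  rel <- csf_partial_volume_effect(fractions = c(csf = 0.10, tissue = 0.90),
                                   diffusivities = D, delta_f_csf = -0.006,
                                   relative = TRUE)
  expect_lt(abs(rel), abs(got))
  sweep <- csf_pve_sweep()
  expect_equal(nrow(sweep$table), length(seq(0.02, 0.5, by = 0.02)))
  expect_equal(sweep$extremum, sweep$table$change[which.max(abs(sweep$table$change))])
  expect_error(csf_partial_volume_effect(fractions = c(csf = 0.5, gm = 0.7)),
               "sum to 1")
})
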