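# A regressor-like object on a uniform grid.
as_reg <- function(values, fs_hz = 50, t0 = -20) {
  structure(list(fs_hz = fs_hz,
                 times_s = t0 + (seq_along(values) - 1) / fs_hz,
                 values = values), class = "petco2_regressor")
}

test_that("lagged correlation: alignment, shift recovery, null magnitude", {
  reg <- small_bold()$regressor
  times <- (1:190) - 0.5
  aligned <- stats::approx(reg$times_s, reg$values, times)$y
  lc <- lagged_correlation(aligned, times, reg)
  expect_equal(lc$r[lc$lag_s == 0], 1, tolerance = 1e-12)
  shifted <- stats::approx(reg$times_s, reg$values, times + 15)$y
  lc2 <- lagged_correlation(shifted, times, reg)
  expect_equal(lc2$lag_s[which.max(lc2$r)], -15, tolerance = 0.5)
  set.seed(99)
  lc3 <- lagged_correlation(stats::rnorm(192), (1:192) - 0.5, reg)
  expect_lt(max(abs(lc3$r), na.rm = TRUE), 0.35)
})

test_that("production lagged correlation matches a naive recomputation", {
  reg <- small_bold()$regressor
  set.seed(4)
  times <- (1:150) - 0.5
  x <- stats::rnorm(150)
  lc <- lagged_correlation(x, times, reg)
  for (i in seq(1, 61, by = 7)) {
    l <- lc$lag_s[i]
    tq <- times - l
    keep <- tq >= reg$times_s[1] & tq <= reg$times_s[length(reg$times_s)]
    g <- stats::approx(reg$times_s, reg$values, tq[keep])$y
    naive <- sum((x[keep] - mean(x[keep])) * (g - mean(g))) /
      sqrt(sum((x[keep] - mean(x[keep]))^2) * sum((g - mean(g))^2))
    expect_equal(lc$r[i], naive, tolerance = 1e-10)
    expect_equal(lc$n[i], sum(keep))
  }
})

test_that("correlation is invariant to scaling and offsets", {
  reg <- small_bold()$regressor
  set.seed(5)
  x <- stats::rnorm(100); times <- (1:100) - 0.5
  r1 <- lagged_correlation(x, times, reg)$r
  r2 <- lagged_correlation(5 * x + 100, times, reg)$r
  reg3 <- reg; reg3$values <- -0.2 * reg$values + 7
  r3 <- lagged_correlation(x, times, reg3)$r
  expect_lt(max(abs(r1 - r2), na.rm = TRUE), 1e-10)
  expect_lt(max(abs(r1 + r3), na.rm = TRUE), 1e-10)  # sign flips with scale < 0
})

test_that("xcorr map recovers noiseless latencies exactly on the lag grid", {
  fx <- small_bold()
  m <- xcorr_map(fx$run, fx$regressor)
  expect_true(all(m$valid))
  expect_true(all(abs(m$rmax) <= 1))
  lat_gm <- unique(m$latency_s[fx$masks$GM])
  lat_wm <- unique(m$latency_s[fx$masks$WM])
  expect_length(lat_gm, 1)
  expect_length(lat_wm, 1)
  expect_equal(lat_wm - lat_gm, 2.5)           # truth separation, exact on grid
  # Fisher z field matches its definition (log form as independent arithmetic)
  sel <- which(m$valid)
  z_alt <- 0.5 * log((1 + m$rmax[sel]) / (1 - m$rmax[sel])) *
    sqrt(m$n_overlap[sel] - 3)
  expect_equal(m$zmax[sel], z_alt, tolerance = 1e-10)
  expect_error(xcorr_map(fx$run, fx$regressor, mask = array(FALSE, c(10, 10, 5))),
               "empty mask")
})

test_that("zmax is monotone in rmax and in N", {
  z <- function(r, n) atanh(r) * sqrt(n - 3)
  r <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(z(r, 100)) > 0))
  n <- seq(20, 200, by = 20)
  expect_true(all(diff(z(0.4, n)) > 0))
  expect_equal(z(0.5, 192), atanh(0.5) * sqrt(189))
  expect_equal(round(z(0.5, 192), 3), 7.552)
})

test_that("peaks at lag-range extremes are marked invalid", {
  reg <- small_bold()$regressor
  times <- (1:150) - 0.5
  x <- stats::approx(reg$times_s, reg$values, times)$y  # true peak at lag 0
  A <- array(rep(x, each = 2), c(2, 1, 1, 150))
  run <- fmri_run(A, TR_s = 1, contrast = "BOLD",
                  masks = list(brain = array(TRUE, c(2, 1, 1)),
                               GM = array(TRUE, c(2, 1, 1))))
  m <- xcorr_map(run, reg)
  expect_equal(m$latency_s[1, 1, 1], 0)
  expect_false(any(m$valid))
})

test_that("grey-matter latency normalization", {
  fx <- small_bold()
  m <- normalize_latency(xcorr_map(fx$run, fx$regressor), fx$masks$GM)
  expect_equal(stats::median(m$latency_s[fx$masks$GM & m$valid]), 0)
  expect_equal(stats::median(m$latency_s[fx$masks$WM & m$valid]), 2.5,
               tolerance = 0.5)
  expect_lt(m$latency_shift_s, 0)
  expect_error(normalize_latency(xcorr_map(fx$run, fx$regressor),
                                 array(FALSE, c(10, 10, 5))),
               "grey-matter")
})

test_that("correlation profiles: single voxel, coherence, and flat null", {
  fx <- small_bold()
  m <- xcorr_map(fx$run, fx$regressor, keep_profiles = TRUE)
  one <- array(FALSE, c(10, 10, 5)); one[which(fx$masks$GM)[1]] <- TRUE
  p1 <- correlation_profile(m, one, gm_mask = fx$masks$GM)
  expect_equal(p1$mean_r, m$per_lag_r[, 1])
  # coherent vascular run: unimodal profile peaking near shifted zero
  pc <- correlation_profile(m, fx$masks$GM, gm_mask = fx$masks$GM)
  expect_lt(abs(pc$lag_s[which.max(pc$mean_r)]), 0.5 + 1e-9)
  # pure-noise run: flat profile
  dims <- c(10, 10, 2); masks <- make_masks(dims)
  gt0 <- make_ground_truth(dims, masks$GM, masks$WM, amp_gm = 0, amp_wm = 0,
                           noise_sigma = 10)
  run0 <- generate_fmri_run("BOLD", gt0, make_vascular_driver(bh_trace()),
                            n_vols = 192, seed = 13)
  m0 <- xcorr_map(run0, fx$regressor, keep_profiles = TRUE)
  p0 <- correlation_profile(m0, masks$brain, gm_mask = NULL)
  expect_gte(sum(masks$brain), 100)
  expect_lt(max(p0$mean_r) - min(p0$mean_r), 0.1)
  expect_warning(correlation_profile(m0, array(FALSE, dims)), "no significant")
})

test_that("run-level latency recovery stays within the lag grid across a noisy cohort", {
  # Per-voxel peak lags jitter by 1-2 s at realistic contrast-to-noise because
  # the correlation profile is flat near its maximum; the quantity the
  # analysis reports (the tissue median per run) recovers truth to within the
  # 0.5 s lag-grid resolution.
  errs <- vapply(1:10, function(s) {
    tr <- generate_co2_trace(resting_spec(440), seed = 300 + s)
    dims <- c(6, 6, 3); masks <- make_masks(dims)
    gt <- make_ground_truth(dims, masks$GM, masks$WM, noise_sigma = 10)
    run <- generate_fmri_run("BOLD", gt, make_vascular_driver(tr),
                             TR_s = 1.1, n_vols = 400, seed = 400 + s)
    run <- highpass_temporal(smooth_spatial(run))
    m <- xcorr_map(run, process_co2(tr))
    gm_err <- abs(stats::median(m$latency_s[masks$GM & m$valid]) -
                    (gt$latency_field[1] - tr$transport_delay_s))
    wm_err <- abs(stats::median(m$latency_s[masks$WM & m$valid]) -
                    (3.5 - tr$transport_delay_s))
    (gm_err + wm_err) / 2
  }, numeric(1))
  expect_lte(mean(errs), 0.5)
})
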