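# Shared fixtures: small, seeded, built once per test run.

fix <- new.env()

bh_trace <- function() {
  if (is.null(fix$bh_trace))
    fix$bh_trace <- generate_co2_trace(generate_breathhold_paradigm(), seed = 42)
  fix$bh_trace
}

rest_trace <- function() {
  if (is.null(fix$rest_trace))
    fix$rest_trace <- generate_co2_trace(resting_spec(), seed = 7)
  fix$rest_trace
}

# Small noiseless breath-hold BOLD run plus its regressor.
small_bold <- function() {
  if (is.null(fix$small_bold)) {
    tr <- bh_trace()
    masks <- make_masks(c(10, 10, 5))
    gt <- make_ground_truth(c(10, 10, 5), masks$GM, masks$WM, noise_sigma = 0)
    run <- generate_fmri_run("BOLD", gt, make_vascular_driver(tr),
                             TR_s = 1, n_vols = 192, seed = 12)
    fix$small_bold <- list(run = run, regressor = process_co2(tr), masks = masks)
  }
  fix$small_bold
}

# Small noiseless diffusion run (T2 coupling only, no IVIM, no neural ADC).
small_dfmri <- function() {
  if (is.null(fix$small_dfmri)) {
    tr <- rest_trace()
    masks <- make_masks(c(8, 8, 4))
    gt <- make_ground_truth(c(8, 8, 4), masks$GM, masks$WM,
                            noise_sigma = 0, ivim_fraction = 0)
    run <- generate_fmri_run("dfmri", gt, make_vascular_driver(tr),
                             TR_s = 1.1, n_pairs = 100, seed = 3)
    fix$small_dfmri <- list(run = run, regressor = process_co2(tr),
                            masks = masks, gt = gt)
  }
  fix$small_dfmri
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol * max(abs(expected), 1e-12))
}
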