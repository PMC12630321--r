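#' fMRI run container
#'
#' A 4D intensity series with acquisition metadata. `volume_times_s` are
#' acquisition mid-times and must be strictly increasing with spacing `TR_s`.
#'
#' @param data 4D array (x, y, z, volume).
#' @param TR_s repetition time (s).
#' @param contrast label: "BOLD", "dfmri", "b200", "b1000" or "ADC".
#' @param b_schedule per-volume b-values (s/mm^2) or `NULL`.
#' @param volume_times_s per-volume times (s); default `(i - 0.5) * TR_s`.
#' @param masks list of logical 3D arrays (`brain`, `GM`, `WM`).
#' @param voxel_size_mm isotropic voxel size (mm).
#' @return class `fmri_run`.
#' @export
fmri_run <- function(data, TR_s, contrast, b_schedule = NULL,
                     volume_times_s = NULL, masks = NULL, voxel_size_mm = 2.8) {
  if (length(dim(data)) != 4) stop("data must be a 4D array", call. = FALSE)
  nv <- dim(data)[4]
  if (is.null(volume_times_s)) volume_times_s <- (seq_len(nv) - 0.5) * TR_s
  if (length(volume_times_s) != nv)
    stop("volume_times_s length must match the number of volumes", call. = FALSE)
  if (any(diff(volume_times_s) <= 0))
    stop("volume_times_s must be strictly increasing", call. = FALSE)
  if (!is.null(b_schedule) && length(b_schedule) != nv)
    stop("b_schedule length must match the number of volumes", call. = FALSE)
  if (!is.null(masks))
    for (m in masks) if (!identical(dim(m), dim(data)[1:3]))
      stop("masks must share the data's 3D grid", call. = FALSE)
  structure(list(data = data, TR_s = TR_s, contrast = contrast,
                 b_schedule = b_schedule, volume_times_s = volume_times_s,
                 masks = masks, voxel_size_mm = voxel_size_mm),
            class = "fmri_run")
}

#' @export
print.fmri_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fmri_run> %s: %d x %d x %d grid, %d volumes, TR %g s\n",
              x$contrast, d[1], d[2], d[3], d[4], x$TR_s))
  invisible(x)
}

# Time x voxel matrix of a run (optionally mask-restricted).
run_matrix <- function(run, mask = NULL) {
  d <- dim(run$data)
  X <- matrix(run$data, prod(d[1:3]), d[4])
  if (!is.null(mask)) X <- X[as.vector(mask), , drop = FALSE]
  t(X)
}

#' Split an interleaved diffusion run into b200 and b1000 series
#'
#' Drops the leading b = 0 volumes and separates the alternating
#' b = 200 / 1000 s/mm^2 volumes into two runs of equal length with
#' effective TR `2 * TR_s`, each keeping its own acquisition times.
#'
#' @param run an `fmri_run` with a `b_schedule`.
#' @return list(`b200`, `b1000`) of `fmri_run` objects.
#' @export
split_dfmri <- function(run) {
  b <- run$b_schedule
  if (is.null(b)) stop("run has no b_schedule", call. = FALSE)
  dw <- which(b != 0)
  if (length(dw) < 2) stop("no complete b200/b1000 pair in the run", call. = FALSE)
  bs <- b[dw]
  if (length(bs) %% 2 != 0 ||
      !all(bs[seq(1, length(bs), by = 2)] == bs[1]) ||
      !all(bs[seq(2, length(bs), by = 2)] == bs[2]) || bs[1] == bs[2])
    stop("b-value schedule is not alternating after the b = 0 lead-in", call. = FALSE)
  lo_first <- bs[1] < bs[2]
  i_low <- dw[seq(if (lo_first) 1 else 2, length(dw), by = 2)]
  i_high <- dw[seq(if (lo_first) 2 else 1, length(dw), by = 2)]
  sub <- function(idx, lab, bval) {
    fmri_run(run$data[, , , idx, drop = FALSE], TR_s = 2 * run$TR_s,
             contrast = lab, b_schedule = rep(bval, length(idx)),
             volume_times_s = run$volume_times_s[idx], masks = run$masks,
             voxel_size_mm = run$voxel_size_mm)
  }
  list(b200 = sub(i_low, "b200", bs[if (lo_first) 1 else 2]),
       b1000 = sub(i_high, "b1000", bs[if (lo_first) 2 else 1]))
}

#' Re-interleave b200/b1000 series (inverse of [split_dfmri()])
#'
#' @param b200,b1000 the two series returned by [split_dfmri()].
#' @return an `fmri_run` holding the alternating diffusion-weighted volumes
#'   (without the b = 0 lead-in).
#' @export
interleave_dfmri <- function(b200, b1000) {
  d <- dim(b200$data)
  n <- d[4]
  out <- array(0, c(d[1:3], 2 * n))
  out[, , , seq(1, 2 * n, by = 2)] <- b200$data
  out[, , , seq(2, 2 * n, by = 2)] <- b1000$data
  times <- numeric(2 * n)
  times[seq(1, 2 * n, by = 2)] <- b200$volume_times_s
  times[seq(2, 2 * n, by = 2)] <- b1000$volume_times_s
  fmri_run(out, TR_s = b200$TR_s / 2, contrast = "dfmri",
           b_schedule = rep(c(b200$b_schedule[1], b1000$b_schedule[1]), n),
           volume_times_s = times, masks = b200$masks,
           voxel_size_mm = b200$voxel_size_mm)
}

#' Compute the ADC timeseries from an interleaved diffusion run
#'
#' For each consecutive (b_low at t, b_high at t + TR) pair,
#' `ADC = -1 / (b_high - b_low) * log(S(b_high) / S(b_low))`, assigned the
#' pair's midpoint time. Any multiplicative modulation shared by the two
#' volumes of a pair (the T2/BOLD weighting) cancels in the ratio, which is
#' the mechanism that makes ADC-fMRI a predominantly non-vascular contrast.
#' Non-positive or non-finite ratios are flagged in `invalid_mask` and set to
#' `NA` rather than clipped.
#'
#' @param run an `fmri_run` with an alternating two-b-value schedule.
#' @return an `fmri_run` with `contrast = "ADC"` (mm^2/s data, effective TR
#'   `2 * TR_s`, pair-midpoint `volume_times_s`) plus fields `b_low`,
#'   `b_high`, and a 4D logical `invalid_mask`.
#' @export
compute_adc_series <- function(run) {
  sp <- split_dfmri(run)
  lo <- sp$b200; hi <- sp$b1000
  if (lo$volume_times_s[1] > hi$volume_times_s[1]) { tmp <- lo; lo <- hi; hi <- tmp }
  b1 <- lo$b_schedule[1]; b2 <- hi$b_schedule[1]
  if (b2 < b1) { tmp <- lo; lo <- hi; hi <- tmp; b1 <- lo$b_schedule[1]; b2 <- hi$b_schedule[1] }
  n <- dim(lo$data)[4]
  if (n < 1) stop("fewer than one complete pair", call. = FALSE)
  ratio <- hi$data / lo$data
  invalid <- !(is.finite(ratio) & ratio > 0 & lo$data > 0 & hi$data > 0)
  adc <- array(NA_real_, dim(ratio))
  adc[!invalid] <- -log(ratio[!invalid]) / (b2 - b1)
  out <- fmri_run(adc, TR_s = 2 * run$TR_s, contrast = "ADC",
                  volume_times_s = (lo$volume_times_s + hi$volume_times_s) / 2,
                  masks = run$masks, voxel_size_mm = run$voxel_size_mm)
  out$b_low <- b1; out$b_high <- b2; out$invalid_mask <- invalid
  out
}

# Two-point ADC of a multi-compartment mixture signal sum(f_i exp(-b D_i)).
mixture_adc <- function(fractions, diffusivities, b_low, b_high) {
  s1 <- sum(fractions * exp(-b_low * diffusivities))
  s2 <- sum(fractions * exp(-b_high * diffusivities))
  -log(s2 / s1) / (b_high - b_low)
}

#' CSF partial-volume effect on the measured ADC
#'
#' Three-compartment estimate of how a change in CSF volume fraction (the
#' Monro-Kellie compensation during the haemodynamic response) would alter
#' the two-point ADC. The mixture signal `sum(f_i exp(-b D_i))` is evaluated
#' at both b-values before and after moving `delta_f_csf` of volume fraction
#' from CSF to the tissue compartments (redistributed proportionally to their
#' fractions), and the fractional ADC change is returned.
#'
#' @param fractions named numeric: compartment volume fractions summing to 1;
#'   the first element is the CSF compartment.
#' @param diffusivities per-compartment diffusivities (mm^2/s), same order.
#'   Defaults: CSF 3.0e-3, GM 0.8e-3, WM 0.75e-3.
#' @param delta_f_csf change in CSF fraction. Interpreted as absolute
#'   fraction points (e.g. -0.006 for a -0.6% change) unless
#'   `relative = TRUE`, in which case it multiplies the CSF fraction.
#' @param b_low,b_high the two b-values (s/mm^2).
#' @param relative interpret `delta_f_csf` relative to the CSF fraction.
#' @return fractional change `(ADC_after - ADC_before) / ADC_before`.
#' @export
csf_partial_volume_effect <- function(fractions = c(csf = 0.10, gm = 0.60, wm = 0.30),
                                      diffusivities = c(csf = 3.0e-3, gm = 0.8e-3,
                                                        wm = 0.75e-3),
                                      delta_f_csf = -0.006,
                                      b_low = 200, b_high = 1000,
                                      relative = FALSE) {
  if (any(fractions < 0 | fractions > 1) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must lie in [0, 1] and sum to 1", call. = FALSE)
  if (any(diffusivities <= 0)) stop("diffusivities must be > 0", call. = FALSE)
  delta <- if (relative) delta_f_csf * fractions[1] else delta_f_csf
  f_after <- fractions
  f_after[1] <- fractions[1] + delta
  if (f_after[1] < 0 || f_after[1] > 1)
    stop("perturbed CSF fraction falls outside [0, 1]", call. = FALSE)
  rest <- fractions[-1]
  if (sum(rest) > 0)
    f_after[-1] <- rest + (-delta) * rest / sum(rest)
  before <- mixture_adc(fractions, diffusivities, b_low, b_high)
  after <- mixture_adc(f_after, diffusivities, b_low, b_high)
  (after - before) / before
}

#' Sweep the CSF partial-volume estimate over a parameter grid
#'
#' Evaluates [csf_partial_volume_effect()] over a grid of CSF fractions and
#' returns the whole table plus the extremum (largest magnitude) change.
#'
#' @param f_csf_grid CSF volume fractions to test.
#' @param ... passed to [csf_partial_volume_effect()].
#' @inheritParams csf_partial_volume_effect
#' @return list(`table` data.frame(f_csf, change), `extremum`).
#' @export
csf_pve_sweep <- function(f_csf_grid = seq(0.02, 0.5, by = 0.02),
                          delta_f_csf = -0.006,
                          diffusivities = c(csf = 3.0e-3, gm = 0.8e-3, wm = 0.75e-3),
                          ...) {
  ch <- vapply(f_csf_grid, function(fc) {
    rest <- (1 - fc) * c(0.6, 0.3) / 0.9
    csf_partial_volume_effect(c(csf = fc, gm = rest[1], wm = rest[2]),
                              diffusivities = diffusivities,
                              delta_f_csf = delta_f_csf, ...)
  }, numeric(1))
  tab <- data.frame(f_csf = f_csf_grid, change = ch)
  list(table = tab, extremum = ch[which.max(abs(ch))])
}
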