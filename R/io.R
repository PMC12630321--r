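# Formats, configuration, orchestration and logging: NIfTI images, physio
# TSV + JSON sidecars, motion tables, the declarative pipeline config, and
# the end-to-end pipeline driver.

#' Read a NIfTI image
#'
#' @param path file path.
#' @param min_dims,max_dims accepted dimensionality (default 3D/4D volumes).
#' @return list(`data` array, `pixdim` voxel dimensions, `image` the RNifti
#'   object carrying the affine/header).
#' @export
read_nifti <- function(path, min_dims = 3, max_dims = 4) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd < min_dims || nd > max_dims)
    stop(sprintf("%s: expected a %d-%dD image, got %dD", path,
                 min_dims, max_dims, nd), call. = FALSE)
  list(data = array(as.numeric(img), dim(img)),
       pixdim = RNifti::pixdim(img), image = img)
}

#' Write a NIfTI image
#'
#' @param data numeric array (3D or 4D).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param pixdim voxel dimensions (mm, plus TR in s for 4D).
#' @export
write_nifti <- function(data, path, pixdim = NULL) {
  img <- RNifti::asNifti(data)
  if (!is.null(pixdim)) RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a physiological recording (TSV + JSON sidecar)
#'
#' Two-column tab-separated file (`time_s`, `co2_mmHg`) with a JSON sidecar
#' carrying `fs_hz`, `start_offset_s` and `trigger_s`.
#'
#' @param trace a `co2_trace`.
#' @param path TSV path; the sidecar replaces the extension with `.json`.
#' @export
write_physio <- function(trace, path) {
  df <- data.frame(time_s = trace$times_s, co2_mmHg = trace$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(fs_hz = trace$fs_hz,
                            start_offset_s = trace$start_offset_s,
                            trigger_s = 0), side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_physio
#' @param path TSV path written by [write_physio()].
#' @export
read_physio <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  side <- jsonlite::read_json(sub("\\.tsv$", ".json", path), simplifyVector = TRUE)
  structure(list(fs_hz = side$fs_hz, values = df$co2_mmHg,
                 start_offset_s = side$start_offset_s, times_s = df$time_s,
                 transport_delay_s = NA_real_),
            class = "co2_trace")
}

#' Write / read a motion-parameter table (6-column TSV)
#'
#' @param motion a `motion_trace`.
#' @param path TSV path.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(as.data.frame(unclass(motion)), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  structure(m, class = c("motion_trace", "matrix"))
}

#' Pipeline configuration
#'
#' Declarative configuration with every published processing default
#' pre-filled: 1 Hz 4th-order low-pass on CO2, cubic detrend, 50 Hz
#' regressor, lag grid -30..0 s in 0.5 s steps, 4 mm FWHM smoothing, 0.01 Hz
#' high-pass, QC at one voxel / 0.2 mm mean FD, 5000 x 5000 surrogate counts
#' (scale down for desk-sized runs), fixed z = 3.09 for breath-hold, and
#' flags for every exposed design alternative.
#'
#' @param ... overrides of the defaults.
#' @return class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    condition = "breathhold",
    contrasts = c("BOLD", "b200", "b1000", "ADC"),
    n_subjects = 3, dims = c(12, 12, 6), seed = 1,
    lag_min_s = -30, lag_max_s = 0, lag_step_s = 0.5,
    co2_lowpass_hz = 1, co2_lowpass_order = 4,
    detrend_order = 3, regressor_fs_hz = 50,
    smooth_fwhm_mm = 4, highpass_hz = 0.01, highpass_order = 4,
    qc_fd_threshold_mm = 0.2, qc_max_disp_voxels = 1,
    n_surrogates = 5000, n_voxels = 5000, surrogate_p = 0.05,
    breathhold_p = 0.001,
    min_overlap = 10,
    # design-decision alternatives
    peak_outlier_two_sided = FALSE, fixed_n = FALSE,
    pool_donors = FALSE, per_voxel_residual_permutation = FALSE,
    motion = list(jitter_mm = 0.02),
    out_dir = NULL, write_images = FALSE
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  if (cfg$lag_min_s >= cfg$lag_max_s) stop("lag_min must be < lag_max", call. = FALSE)
  if (cfg$lag_step_s <= 0) stop("lag step must be positive", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Sequences the stages — physio regressor, contrast splitting/ADC,
#' conditioning (smoothing + high-pass), motion QC, lag mapping, surrogate
#' thresholds (resting) or the fixed breath-hold threshold, and the summary
#' statistics — for every run of every subject, and assembles a report with
#' versions, seeds, QC decisions, thresholds and metrics. QC-rejected runs
#' are excluded downstream and listed. With `out_dir` set, metric tables
#' (TSV), the report (JSON) and optionally NIfTI maps are written.
#'
#' @param config a [pipeline_config()].
#' @return the report (list), invisibly also written to
#'   `out_dir/report.json` when `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  lags <- seq(cfg$lag_min_s, cfg$lag_max_s, by = cfg$lag_step_s)
  cohort <- simulate_cohort(n_subjects = cfg$n_subjects, condition = cfg$condition,
                            dims = cfg$dims, seed = cfg$seed)
  report <- list(package_version = as.character(utils::packageVersion("petco2lag")),
                 seed = cfg$seed, condition = cfg$condition,
                 config = unclass(cfg), qc = list(), thresholds = list(),
                 stage_log = character(0))
  metrics <- data.frame()
  maps_by_contrast <- list()
  rejected <- character(0)

  for (sub in cohort) {
    regressor <- process_co2(sub$trace)
    motion <- generate_motion(dim(sub$runs$BOLD$data)[4],
                              jitter_mm = cfg$motion$jitter_mm,
                              seed = sub$seed + 7)
    qc <- qc_gate(motion, voxel_size_mm = sub$runs$BOLD$voxel_size_mm *
                    cfg$qc_max_disp_voxels,
                  fd_threshold_mm = cfg$qc_fd_threshold_mm)
    report$qc[[sprintf("subject%02d", sub$subject)]] <-
      list(accepted = qc$accepted, mean_fd_mm = qc$mean_fd_mm,
           max_abs_displacement_mm = qc$max_abs_displacement_mm,
           reasons = qc$reasons)
    if (!qc$accepted) {
      rejected <- c(rejected, sprintf("subject%02d", sub$subject))
      next
    }
    sp <- split_dfmri(sub$runs$dfmri)
    series <- list(BOLD = sub$runs$BOLD, b200 = sp$b200, b1000 = sp$b1000,
                   ADC = compute_adc_series(sub$runs$dfmri))
    for (ct in cfg$contrasts) {
      run <- series[[ct]]
      run <- smooth_spatial(run, cfg$smooth_fwhm_mm)
      run <- highpass_temporal(run, cfg$highpass_hz, cfg$highpass_order)
      map <- xcorr_map(run, regressor, mask = run$masks$brain, lags = lags,
                       min_overlap = cfg$min_overlap, fixed_n = cfg$fixed_n)
      map <- normalize_latency(map, run$masks$GM)
      maps_by_contrast[[ct]][[sub$subject]] <- map
      entry <- list(subject = sub$subject, contrast = ct, map = map,
                    run = run, regressor = regressor)
      maps_by_contrast[[paste0(ct, "_entries")]][[sub$subject]] <- entry
    }
    report$stage_log <- c(report$stage_log,
                          sprintf("subject%02d: physio/contrast/conditioning/lagmap done",
                                  sub$subject))
  }
  report$rejected_runs <- rejected

  processed <- setdiff(seq_len(cfg$n_subjects),
                       as.integer(sub("subject", "", rejected)))
  if (length(processed) == 0) {
    report$stats <- "all runs rejected by QC; statistics stage skipped"
    if (!is.null(cfg$out_dir)) write_report(report, metrics, cfg$out_dir)
    return(report)
  }

  for (ct in cfg$contrasts) {
    if (cfg$condition == "breathhold") {
      zthr <- round(breathhold_z_threshold(cfg$breathhold_p), 2)
    } else {
      entries <- Filter(Negate(is.null), maps_by_contrast[[paste0(ct, "_entries")]])
      null <- build_null(lapply(entries, function(e)
        list(regressor = e$regressor, run = e$run)),
        n_surrogates = cfg$n_surrogates, n_voxels = cfg$n_voxels,
        seed = cfg$seed, lags = lags, pool_donors = cfg$pool_donors)
      zthr <- significance_threshold(null, cfg$surrogate_p)
      report$surrogate_seeds[[ct]] <- null$seeds
    }
    report$thresholds[[ct]] <- zthr
    for (s in processed) {
      map <- maps_by_contrast[[ct]][[s]]
      mask <- map$mask
      metrics <- rbind(metrics, data.frame(
        subject = s, contrast = ct,
        pct_significant = percent_significant(map, mask, zthr),
        mean_r2 = mean_variance_explained(map, mask),
        latency_shift_s = map$latency_shift_s, zthresh = zthr))
    }
  }
  report$metrics <- metrics
  if (!is.null(cfg$out_dir)) write_report(report, metrics, cfg$out_dir,
                                          maps_by_contrast, cfg)
  report
}

write_report <- function(report, metrics, out_dir, maps = NULL, cfg = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(metrics))
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  clean <- report
  clean$metrics <- NULL
  jsonlite::write_json(clean, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!is.null(maps) && !is.null(cfg) && isTRUE(cfg$write_images)) {
    for (ct in cfg$contrasts) {
      for (s in seq_along(maps[[ct]])) {
        m <- maps[[ct]][[s]]
        if (is.null(m)) next
        write_nifti(m$zmax, file.path(out_dir, sprintf("sub%02d_%s_zmax.nii.gz", s, ct)))
        write_nifti(m$latency_s, file.path(out_dir, sprintf("sub%02d_%s_latency.nii.gz", s, ct)))
      }
    }
  }
  invisible(out_dir)
}
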