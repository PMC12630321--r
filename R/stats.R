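# Summary metrics, reproducibility/similarity analysis, and
# between-contrast tests.

#' Breath-hold significance threshold
#'
#' The fixed one-tailed standard-normal critical value used for breath-hold
#' maps (surrogate thresholds are unusable there because the task frequency
#' dominates every pETCO2 trace): `qnorm(1 - p)`, 3.09 at p = 0.001.
#'
#' @param p one-tailed significance level.
#' @export
breathhold_z_threshold <- function(p = 0.001) stats::qnorm(1 - p)

#' Percentage of significant voxels
#'
#' `100 * #{in-mask voxels that are valid and have zmax > zthresh} / #mask`.
#'
#' @param map an `xcorr_map` (or a 3D zmax array, in which case every finite
#'   voxel counts as valid).
#' @param mask logical 3D array (denominator).
#' @param zthresh z threshold (strict inequality).
#' @export
percent_significant <- function(map, mask, zthresh) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (inherits(map, "xcorr_map")) {
    z <- map$zmax; valid <- map$valid
  } else {
    z <- map; valid <- is.finite(map)
  }
  100 * sum(valid[mask] & z[mask] > zthresh, na.rm = TRUE) / sum(mask)
}

#' Mean variance explained (percent)
#'
#' `100 * mean(rmax^2)` over valid in-mask voxels (boundary-excluded voxels
#' are omitted; set `significant_only` with a threshold to average over
#' significant voxels instead).
#'
#' @param map an `xcorr_map`.
#' @param mask logical 3D array.
#' @param significant_only optional z threshold restricting the average.
#' @export
mean_variance_explained <- function(map, mask, significant_only = NULL) {
  sel <- map$valid & mask
  if (!is.null(significant_only)) sel <- sel & map$zmax > significant_only
  if (!any(sel)) stop("no valid voxels in mask", call. = FALSE)
  100 * mean(map$rmax[sel]^2)
}

#' Average xcorr maps across runs of one subject
#'
#' Voxelwise mean of `zmax` (and `rmax`, `latency_s`) over runs, restricted
#' to voxels valid in every run; validity is propagated by conjunction.
#'
#' @param maps list of `xcorr_map`s on a shared grid.
#' @return an `xcorr_map`-like averaged map.
#' @export
average_subject_maps <- function(maps) {
  dims <- lapply(maps, function(m) dim(m$zmax))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("maps are not on a shared grid", call. = FALSE)
  valid <- Reduce(`&`, lapply(maps, `[[`, "valid"))
  avg <- function(field) {
    a <- Reduce(`+`, lapply(maps, `[[`, field)) / length(maps)
    a[!valid] <- NA_real_
    a
  }
  structure(list(rmax = avg("rmax"), latency_s = avg("latency_s"),
                 zmax = avg("zmax"), n_overlap = avg("n_overlap"),
                 valid = valid, lags = maps[[1]]$lags, mask = maps[[1]]$mask,
                 contrast = maps[[1]]$contrast,
                 latency_shift_s = mean(vapply(maps, `[[`, numeric(1),
                                               "latency_shift_s"))),
            class = "xcorr_map")
}

#' Similarity between two maps
#'
#' z-transformed Pearson correlation (`atanh(r)`) between voxelwise values of
#' two maps over the shared valid in-mask voxels; `r` is clipped to
#' `+/-(1 - 1e-12)` before the transform and `|r| = 1` pairs are flagged
#' `degenerate` rather than erroring (so duplicated-run smoke checks pass).
#' Constant inputs are a degeneracy error.
#'
#' @param map_a,map_b `xcorr_map`s (their `zmax` is compared) or 3D arrays.
#' @param mask logical 3D array.
#' @param min_voxels minimum shared valid voxels.
#' @return the z-transformed correlation, with attribute `degenerate`.
#' @export
map_similarity <- function(map_a, map_b, mask, min_voxels = 10) {
  get <- function(m) if (inherits(m, "xcorr_map")) list(v = m$zmax, ok = m$valid)
                     else list(v = m, ok = is.finite(m))
  a <- get(map_a); b <- get(map_b)
  sel <- a$ok & b$ok & mask
  if (sum(sel) < min_voxels)
    stop("fewer shared valid voxels than min_voxels", call. = FALSE)
  x <- a$v[sel]; y <- b$v[sel]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant map: similarity undefined", call. = FALSE)
  r <- stats::cor(x, y)
  degenerate <- abs(r) >= 1 - 1e-12
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  structure(atanh(r), degenerate = degenerate)
}

#' Intra-subject, inter-subject and cross-condition map similarity
#'
#' For a cohort of labelled maps: intra-subject similarity between pairs of
#' breath-hold runs of the same subject; inter-subject similarity as each
#' subject's mean similarity from its run-averaged map to every other
#' subject's (per condition); and cross-condition (within-subject) similarity
#' between the breath-hold run-average and the resting map. Subjects with
#' missing runs are skipped with a log entry.
#'
#' @param entries list of entries: list(`subject`, `run`, `condition`
#'   ("breathhold"/"resting"), `map` an `xcorr_map`).
#' @param mask logical 3D array.
#' @return list of data.frames `intra_subject`, `inter_subject`,
#'   `cross_condition`, plus `skipped` (character log).
#' @export
similarity_suite <- function(entries, mask) {
  subj <- vapply(entries, `[[`, numeric(1), "subject")
  cond <- vapply(entries, `[[`, character(1), "condition")
  skipped <- character(0)
  subjects <- sort(unique(subj))

  bh_avg <- list(); rs_map <- list()
  intra <- data.frame(subject = numeric(0), similarity = numeric(0))
  for (s in subjects) {
    bh <- entries[subj == s & cond == "breathhold"]
    rs <- entries[subj == s & cond == "resting"]
    if (length(bh) >= 2) {
      sim <- map_similarity(bh[[1]]$map, bh[[2]]$map, mask)
      intra <- rbind(intra, data.frame(subject = s, similarity = as.numeric(sim)))
    } else if (length(bh) == 1) {
      skipped <- c(skipped, sprintf("subject %g: single breath-hold run, intra-subject skipped", s))
    }
    if (length(bh) >= 1)
      bh_avg[[as.character(s)]] <- average_subject_maps(lapply(bh, `[[`, "map"))
    if (length(rs) >= 1) rs_map[[as.character(s)]] <- rs[[1]]$map
  }

  inter_of <- function(maps_by_subj, condition) {
    ids <- names(maps_by_subj)
    if (length(ids) < 2) return(NULL)
    do.call(rbind, lapply(ids, function(s) {
      others <- setdiff(ids, s)
      sims <- vapply(others, function(o)
        as.numeric(map_similarity(maps_by_subj[[s]], maps_by_subj[[o]], mask)),
        numeric(1))
      data.frame(subject = as.numeric(s), condition = condition,
                 mean_similarity = mean(sims))
    }))
  }
  inter <- rbind(inter_of(bh_avg, "breathhold"), inter_of(rs_map, "resting"))

  cross <- do.call(rbind, lapply(subjects, function(s) {
    key <- as.character(s)
    if (is.null(bh_avg[[key]]) || is.null(rs_map[[key]])) {
      skipped <<- c(skipped, sprintf("subject %g: missing condition, cross-condition skipped", s))
      return(NULL)
    }
    data.frame(subject = s,
               similarity = as.numeric(map_similarity(bh_avg[[key]],
                                                      rs_map[[key]], mask)))
  }))
  list(intra_subject = intra, inter_subject = inter,
       cross_condition = cross, skipped = skipped)
}

#' Pairwise between-contrast tests
#'
#' Two-tailed unpaired Mann-Whitney U tests (exact for small samples without
#' ties, normal approximation otherwise) between every pair of contrasts,
#' with Bonferroni correction: p multiplied by the family size (default the
#' number of contrast pairs), capped at 1. Groups with fewer than 3 values
#' are skipped with a warning.
#'
#' @param values numeric metric values.
#' @param groups contrast label per value.
#' @param n_comparisons Bonferroni family size; default `choose(k, 2)` over
#'   the k supplied groups.
#' @return data.frame(`group_a`, `group_b`, `U`, `p_raw`, `p_bonf`).
#' @export
pairwise_tests <- function(values, groups, n_comparisons = NULL) {
  groups <- as.character(groups)
  levs <- unique(groups)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  if (is.null(n_comparisons)) n_comparisons <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
    if (length(a) < 3 || length(b) < 3) {
      warning(sprintf("skipping %s vs %s: fewer than 3 values per group",
                      pr[1], pr[2]))
      return(NULL)
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    data.frame(group_a = pr[1], group_b = pr[2], U = unname(wt$statistic),
               p_raw = wt$p.value, p_bonf = min(1, wt$p.value * n_comparisons))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(group_a = character(0), group_b = character(0),
                                      U = numeric(0), p_raw = numeric(0),
                                      p_bonf = numeric(0))
  out
}

#' Summary metrics for one map
#'
#' @param map an `xcorr_map`.
#' @param mask logical 3D array.
#' @param zthresh z threshold used for the significant-voxel percentage.
#' @return data.frame(`pct_significant`, `mean_r2`, `zthresh`, `contrast`).
#' @export
summary_metrics <- function(map, mask, zthresh) {
  data.frame(pct_significant = percent_significant(map, mask, zthresh),
             mean_r2 = mean_variance_explained(map, mask),
             zthresh = zthresh, contrast = map$contrast %||% NA_character_)
}
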