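# Minimal xcorr_map-like object for metric tests.
mk_map <- function(z, valid = is.finite(z), r = tanh(z / 10)) {
  structure(list(rmax = r, latency_s = z * 0, zmax = z,
                 n_overlap = z * 0 + 100, valid = valid,
                 lags = seq(-30, 0, 0.5), mask = array(TRUE, dim(z)),
                 contrast = "test", latency_shift_s = 0), class = "xcorr_map")
}

test_that("percent significant: counting, monotone threshold sweep", {
  dims <- c(10, 10, 1)
  mask <- array(TRUE, dims)
  z0 <- array(0, dims)
  expect_equal(percent_significant(mk_map(z0), mask, 3.09), 0)
  z1 <- array(0, dims); z1[1:10] <- 5
  expect_equal(percent_significant(mk_map(z1), mask, 3.09), 10)
  set.seed(1)
  zr <- array(stats::rnorm(100, 2.5, 0.8), dims)
  sweep <- vapply(seq(2.0, 3.5, by = 0.1),
                  function(th) percent_significant(mk_map(zr), mask, th),
                  numeric(1))
  expect_true(all(diff(sweep) <= 0))
  expect_error(percent_significant(mk_map(z0), array(FALSE, dims), 3), "empty")
  # permutation invariance to voxel ordering
  perm <- sample(100)
  zp <- array(zr[perm], dims)
  expect_equal(percent_significant(mk_map(zp), mask, 2.5),
               percent_significant(mk_map(zr), mask, 2.5))
})

test_that("mean variance explained", {
  dims <- c(3, 1, 1)
  m <- mk_map(array(1, dims), r = array(c(0.2, 0.4, 0.6), dims))
  expect_equal(mean_variance_explained(m, array(TRUE, dims)),
               mean(c(4, 16, 36)))
  m2 <- mk_map(array(1, dims), r = array(0.5, dims))
  expect_equal(mean_variance_explained(m2, array(TRUE, dims)), 25)
  m3 <- mk_map(array(1, dims), r = array(0, dims))
  expect_equal(mean_variance_explained(m3, array(TRUE, dims)), 0)
  m4 <- mk_map(array(NA_real_, dims), valid = array(FALSE, dims))
  expect_error(mean_variance_explained(m4, array(TRUE, dims)), "no valid")
})

test_that("run averaging restricts to jointly valid voxels", {
  dims <- c(2, 2, 1)
  a <- mk_map(array(2, dims)); b <- mk_map(array(4, dims))
  avg <- average_subject_maps(list(a, b))
  expect_equal(avg$zmax[1, 1, 1], 3)
  expect_identical(average_subject_maps(list(a, a))$zmax, a$zmax)
  b$valid[1, 1, 1] <- FALSE
  avg2 <- average_subject_maps(list(a, b))
  expect_false(avg2$valid[1, 1, 1])
  expect_true(is.na(avg2$zmax[1, 1, 1]))
  bad <- mk_map(array(1, c(3, 3, 1)))
  expect_error(average_subject_maps(list(a, bad)), "shared grid")
})

test_that("map similarity: exact Fisher z, degeneracy handling", {
  dims <- c(20, 20, 25)
  n <- prod(dims)
  set.seed(3)
  x <- as.vector(scale(stats::rnorm(n)))
  e <- stats::rnorm(n)
  e <- as.vector(scale(e - x * sum(e * x) / sum(x^2)))   # exactly orthogonal
  y <- 0.5 * x + sqrt(0.75) * e                          # empirical r = 0.5
  A <- array(x, dims); B <- array(y, dims)
  mask <- array(TRUE, dims)
  s <- map_similarity(A, B, mask)
  expect_equal(as.numeric(s), atanh(0.5), tolerance = 1e-10)
  expect_equal(round(as.numeric(s), 4), 0.5493)
  # independent noise: similarity near zero at 10^4 voxels
  s0 <- map_similarity(A, array(stats::rnorm(n), dims), mask)
  expect_lt(abs(as.numeric(s0)), 0.1)
  # identical maps: clipped large finite value, flagged degenerate
  sd_ <- map_similarity(A, A, mask)
  expect_true(attr(sd_, "degenerate"))
  expect_true(is.finite(as.numeric(sd_)))
  expect_error(map_similarity(array(1, dims), B, mask), "constant")
})

test_that("similarity suite: structure, degenerate flags, skipping", {
  dims <- c(8, 8, 4)
  mask <- array(TRUE, dims)
  set.seed(6)
  shared <- array(stats::rnorm(prod(dims)), dims)
  noisy <- function(sd) mk_map(shared + array(stats::rnorm(prod(dims), 0, sd), dims))
  pure_noise <- function() mk_map(array(stats::rnorm(prod(dims)), dims))
  entries <- list(
    list(subject = 1, run = 1, condition = "breathhold", map = noisy(0.3)),
    list(subject = 1, run = 2, condition = "breathhold", map = noisy(0.3)),
    list(subject = 1, run = 1, condition = "resting", map = noisy(0.5)),
    list(subject = 2, run = 1, condition = "breathhold", map = noisy(0.3)),
    list(subject = 2, run = 2, condition = "breathhold", map = noisy(0.3)),
    list(subject = 2, run = 1, condition = "resting", map = noisy(0.5)),
    list(subject = 3, run = 1, condition = "breathhold", map = pure_noise()),
    list(subject = 3, run = 2, condition = "breathhold", map = pure_noise()),
    list(subject = 3, run = 1, condition = "resting", map = pure_noise()))
  out <- similarity_suite(entries, mask)
  expect_equal(nrow(out$intra_subject), 3)
  expect_equal(nrow(out$cross_condition), 3)
  inter_bh <- out$inter_subject[out$inter_subject$condition == "breathhold", ]
  # subjects sharing coupling truth resemble each other more than the noise one
  expect_gt(min(inter_bh$mean_similarity[inter_bh$subject %in% 1:2]),
            inter_bh$mean_similarity[inter_bh$subject == 3])
  expect_gt(min(out$intra_subject$similarity[1:2]),
            out$intra_subject$similarity[3])
  # duplicated run: intra-subject similarity is degenerate-high but finite
  dup <- similarity_suite(list(
    list(subject = 1, run = 1, condition = "breathhold", map = noisy(0.3)),
    list(subject = 1, run = 1, condition = "breathhold",
         map = entries[[1]]$map)), mask)
  expect_true(all(is.finite(dup$intra_subject$similarity)))
  # single-run subject skipped with a log entry
  skip <- similarity_suite(entries[c(1, 4, 5)], mask)
  expect_match(paste(skip$skipped, collapse = " "), "single breath-hold")
})

test_that("Mann-Whitney tests: exact enumeration oracle and Bonferroni", {
  # independent oracle: enumerate all C(6,3) = 20 group assignments
  vals <- c(1, 2, 3, 4, 5, 6)
  obs_u <- function(a) {
    b <- setdiff(vals, a)
    sum(outer(a, b, ">"))
  }
  combos <- utils::combn(vals, 3, simplify = FALSE)
  u_obs <- obs_u(c(1, 2, 3))
  u_all <- vapply(combos, obs_u, numeric(1))
  p_exact <- mean(u_all <= u_obs | u_all >= (9 - u_obs))   # two-tailed
  expect_equal(p_exact, 0.1)
  out <- pairwise_tests(vals, rep(c("A", "B"), each = 3), n_comparisons = 6)
  expect_equal(out$U, 0)
  expect_equal(out$p_raw, 0.1)
  expect_equal(out$p_bonf, 0.6)
  # label swap leaves the two-tailed p unchanged
  out2 <- pairwise_tests(vals, rep(c("B", "A"), each = 3), n_comparisons = 6)
  expect_equal(out2$p_raw, out$p_raw)
  # identical groups: p capped at 1
  out3 <- suppressWarnings(
    pairwise_tests(rep(c(1, 2, 3), 2), rep(c("A", "B"), each = 3),
                   n_comparisons = 6))
  expect_equal(out3$p_bonf, 1)
  expect_warning(pairwise_tests(c(1, 2, 1, 2), c("A", "A", "B", "B")),
                 "fewer than 3")
})
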