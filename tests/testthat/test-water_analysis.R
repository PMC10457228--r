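test_that("water estimator follows the band-ratio formula", {
  ax <- coarse_axis()
  cfg <- analysis_config(water_cal_r = 1)
  # no OH signal -> w = 0
  ch_only <- exp(-(ax - 2935)^2 / (2 * 15^2))
  expect_equal(estimate_water(ch_only, ax, cfg), 0)
  # rho = R -> w = 0.5 exactly: build a spectrum with equal band areas
  oh_only <- exp(-(ax - 3450)^2 / (2 * 30^2))
  r <- band_area(ax, oh_only, cfg$oh_band) / band_area(ax, ch_only, cfg$ch_band)
  expect_equal(estimate_water(ch_only + oh_only / r, ax, cfg), 0.5)
  # non-positive CH area -> invalid estimate
  expect_true(is.na(estimate_water(-ch_only, ax, cfg)))
  # R rescales the mapping: with R = rho the same spectrum reads 0.5
  s <- ch_only + oh_only
  rho <- band_area(ax, s, cfg$oh_band) / band_area(ax, s, cfg$ch_band)
  expect_equal(estimate_water(s, ax, analysis_config(water_cal_r = rho)), 0.5)
})

test_that("the outlier rule discards strictly above the ceiling", {
  wm <- structure(list(w = matrix(0.75, 3, 3), valid = matrix(TRUE, 3, 3),
                       smoothed = NULL, n_discarded_outlier = NA, map_id = "t"),
                  class = "water_map")
  expect_equal(apply_outlier_rule(wm)$n_discarded_outlier, 0)
  wm$w[2, 2] <- 0.88   # exactly at the ceiling: retained
  expect_equal(apply_outlier_rule(wm)$n_discarded_outlier, 0)
  wm$w[2, 2] <- 0.89
  out <- apply_outlier_rule(wm)
  expect_equal(out$n_discarded_outlier, 1)
  expect_false(out$valid[2, 2])
  expect_true(is.na(out$w[2, 2]))
})

test_that("3x3 smoothing averages valid neighbours with edge handling", {
  mk <- function(w, valid = matrix(TRUE, nrow(w), ncol(w)))
    structure(list(w = w, valid = valid, smoothed = NULL,
                   n_discarded_outlier = 0, map_id = "t"),
              class = "water_map")
  # constant map unchanged
  cm <- smooth_map(mk(matrix(0.6, 5, 5)))
  expect_equal(cm$smoothed, matrix(0.6, 5, 5))
  # single interior impulse spreads to 1/9 over its neighbourhood
  w <- matrix(0, 5, 5); w[3, 3] <- 1
  sm <- smooth_map(mk(w))$smoothed
  expect_equal(sm[2:4, 2:4], matrix(1 / 9, 3, 3))
  expect_equal(sm[1, 1], 0)
  # corner pixel averages over its 4 in-bounds neighbours
  w2 <- matrix(0, 4, 4); w2[1, 1] <- 1
  expect_equal(smooth_map(mk(w2))$smoothed[1, 1], 1 / 4)
  # invalid neighbours are omitted; invalid pixels are never imputed
  w3 <- matrix(1, 3, 3); v3 <- matrix(TRUE, 3, 3); v3[2, 2] <- FALSE
  w3[2, 2] <- NA
  sm3 <- smooth_map(mk(w3, v3))
  expect_true(is.na(sm3$smoothed[2, 2]))
  expect_equal(sm3$smoothed[1, 1], 1)
  # brute-force oracle on a random fully-valid map
  set.seed(8)
  w4 <- matrix(runif(30), 5, 6)
  sm4 <- smooth_map(mk(w4))$smoothed
  brute <- matrix(NA_real_, 5, 6)
  for (r in 1:5) for (c in 1:6)
    brute[r, c] <- mean(w4[max(1, r - 1):min(5, r + 1),
                           max(1, c - 1):min(6, c + 1)])
  expect_equal(sm4, brute)
})

test_that("group collection selects unambiguous valid pixels and conserves counts", {
  w <- matrix(0.7, 4, 5)
  valid <- matrix(TRUE, 4, 5)
  wm <- structure(list(w = w, valid = valid, smoothed = NULL,
                       n_discarded_outlier = 0, map_id = "t"),
                  class = "water_map")
  lab <- matrix("MUSCLE", 4, 5)
  lab[1:2, ] <- "TUMOR"
  lab[4, 5] <- "AMBIGUOUS"; lab[4, 4] <- "BACKGROUND"
  g <- collect_groups(wm, annotation_mask(lab))
  expect_length(g$tumor, 10)
  expect_length(g$noncancer, 8)
  expect_equal(sum(lengths(g$per_type)), 18)
  expect_error(collect_groups(wm, annotation_mask(matrix("AMBIGUOUS", 4, 5))),
               "no valid pixels")
})

test_that("the rank-sum comparison matches exact enumeration and the AUC oracle", {
  g <- function(x, y) structure(list(tumor = x, noncancer = y,
                                     per_type = list()),
                                class = "grouped_water")
  res <- compare_water(g(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$p_value, 0.1)     # exact two-sided, all 20 orderings
  expect_equal(res$auc, 0)           # tumor scores all lower
  res2 <- compare_water(g(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(res2$auc, 1)
  expect_equal(res2$p_value, 0.1)

  # identical groups: ties give AUC 0.5, p 1
  res3 <- compare_water(g(rep(1, 5), rep(1, 7)))
  expect_equal(res3$auc, 0.5)
  expect_equal(res3$p_value, 1)

  # swap antisymmetry and Mann-Whitney oracle on random fixtures
  set.seed(17)
  for (i in 1:20) {
    x <- round(rnorm(25, 0.2), 1); y <- round(rnorm(30), 1)  # with ties
    a <- compare_water(g(x, y))
    b <- compare_water(g(y, x))
    expect_equal(a$auc, 1 - b$auc, tolerance = 1e-12)
    expect_equal(a$auc, mw_auc(c(x, y), rep(c(TRUE, FALSE), c(25, 30))),
                 tolerance = 1e-12)
    expect_equal(a$p_value,
                 stats::wilcox.test(x, y, exact = FALSE,
                                    correct = FALSE)$p.value)
  }
  expect_error(compare_water(g(numeric(0), c(1, 2))), "non-empty")
})

test_that("water maps from synthetic pixels recover the generated fractions", {
  prof <- coarse_profiles()
  entry <- make_test_entry(seed = 31, nr = 6, nc = 6, snr = Inf,
                           profiles = prof)
  # remove the (noise-free) background first
  m <- entry$map
  for (i in seq_len(nrow(m$spectra)))
    m$spectra[i, ] <- subtract_background(m$spectra[i, ], m$axis)
  wm <- compute_water_map(m, analysis_config(water_cal_r = prof$cal_r))
  est <- as.vector(t(wm$w))
  # baseline removal under the broad OH band leaves a small residual bias
  expect_lt(max(abs(est - entry$truth$water), na.rm = TRUE), 0.1)
  expect_lt(mean(abs(est - entry$truth$water), na.rm = TRUE), 0.04)
})
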