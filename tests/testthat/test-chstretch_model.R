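test_that("EMSC recovers constructed coefficients and is a fixed point on the reference", {
  prof <- coarse_profiles()
  win <- restrict_window(matrix(prof$profiles["TUMOR", ], 1), prof$axis)
  set.seed(4)
  base <- t(sapply(1:30, function(i)
    make_pixel_spectrum(prof, "CONNECTIVE", runif(1, 0.6, 0.9), snr = 40)))
  rw <- restrict_window(base, prof$axis)
  wi <- water_interferent(prof)
  em <- emsc_model(rw$spectra, rw$axis, interferents = wi$spectrum)
  m <- em$reference

  # reference fixed point
  expect_equal(emsc_correct(m, em), m, tolerance = 1e-10)
  # s = 2m + 0.3 g_water -> m exactly
  g <- em$interferents[, 1]
  expect_equal(emsc_correct(2 * m + 0.3 * g, em), m, tolerance = 1e-9)
  # pure offset absorbed by the baseline term
  expect_equal(emsc_correct(m + 5, em), m, tolerance = 1e-9)
  # degenerate spectrum (no reference signal) errors / is flagged
  expect_error(emsc_correct(g * 1e-12, em), "degenerate")
  flagged <- emsc_correct_matrix(rbind(m, g * 0), em)
  expect_equal(flagged$valid, c(TRUE, FALSE))
  expect_true(all(is.na(flagged$corrected[2, ])))
})

test_that("EMSC output is invariant to scaling and to added water interferent", {
  prof <- coarse_profiles()
  set.seed(14)
  sp <- t(sapply(1:40, function(i)
    make_pixel_spectrum(prof, sample(ANALYSIS_LABELS, 1), runif(1, 0.5, 0.88),
                        snr = 20)))
  rw <- restrict_window(sp, prof$axis)
  wi <- water_interferent(prof)
  em <- emsc_model(rw$spectra, rw$axis, interferents = wi$spectrum)
  for (i in sample(40, 10)) {
    s <- rw$spectra[i, ]
    ref <- emsc_correct(s, em)
    kappa <- runif(1, 0.1, 5)
    expect_lt(sqrt(mean((emsc_correct(kappa * s, em) - ref)^2)), 1e-8)
    cc <- runif(1, 0, 2)
    expect_lt(sqrt(mean((emsc_correct(s + cc * wi$spectrum, em) - ref)^2)),
              1e-8)
  }
  # rank-deficient design is rejected
  expect_error(emsc_model(rw$spectra, rw$axis,
                          interferents = cbind(wi$spectrum, wi$spectrum)),
               "rank deficient")
})

test_that("Savitzky-Golay filtering preserves cubics and contracts noise", {
  x <- seq(-1, 1, length.out = 120)
  cubic <- 1 - 2 * x + 0.5 * x^2 + 3 * x^3
  expect_lt(max(abs(sg_filter(cubic) - cubic)), 1e-10)
  const <- rep(2.5, 50)
  expect_equal(sg_filter(const), const, tolerance = 1e-12)
  set.seed(2)
  noise <- rnorm(1000)
  expect_lt(var(sg_filter(noise)), var(noise))
  expect_error(sg_filter(rnorm(5)), "window")
  expect_error(sg_filter(rnorm(50), window = 10), "odd")
})

test_that("matrix SG path equals the per-vector reference filter", {
  set.seed(3)
  Y <- matrix(rnorm(5 * 60), 5, 60)
  M <- sg_filter(Y)
  for (i in 1:5)
    expect_equal(M[i, ], sg_filter(Y[i, ]), tolerance = 1e-12)
})

test_that("PCA colour maps separate regions and handle degenerate input", {
  prof <- coarse_profiles()
  valid <- matrix(TRUE, 6, 6)
  lab <- two_class_grid(6, 6)
  sp <- t(sapply(as.vector(t(lab)), function(t)
    make_pixel_spectrum(prof, t, 0.75, snr = Inf)))
  rw <- restrict_window(sp, prof$axis)
  img <- pca_rgb_map(rw$spectra, valid)
  expect_equal(dim(img), c(6, 6, 3))
  expect_true(all(img >= 0 & img <= 1))
  # within-region variance below between-region variance on PC1 channel
  ch1 <- img[, , 1]
  tum <- ch1[1:3, ]; mus <- ch1[4:6, ]
  expect_lt(var(as.vector(tum)) + var(as.vector(mus)),
            (mean(tum) - mean(mus))^2)
  # all-identical spectra: flat mid-gray, no crash
  same <- matrix(rep(rw$spectra[1, ], 36), 36, byrow = TRUE)
  img2 <- pca_rgb_map(same, valid)
  expect_true(all(img2 == 0.5))
  expect_error(pca_rgb_map(rw$spectra[1:2, ], matrix(TRUE, 1, 2)), "3 valid")
})

test_that("PCA-LDA separates separable classes and matches a brute-force p = 1 oracle", {
  set.seed(6)
  n <- 120
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  base <- matrix(rnorm(n * 20), n, 20)
  base[lab, 1] <- base[lab, 1] + 8   # separable along one direction
  fit <- fit_pcalda(base, lab, p = 3)
  expect_equal(roc_curve(score_spectra(fit, base), lab)$auc, 1.0)
  expect_gt(mean(score_spectra(fit, base)[lab]),
            mean(score_spectra(fit, base)[!lab]))

  # p = 1: equals LDA on PC1 scores computed from scratch
  fit1 <- fit_pcalda(base, lab, p = 1)
  pc1 <- sweep(base, 2, colMeans(base)) %*%
    eigen(cov(base))$vectors[, 1, drop = FALSE]
  mu1 <- mean(pc1[lab]); mu0 <- mean(pc1[!lab])
  sw <- sum((pc1[lab] - mu1)^2) + sum((pc1[!lab] - mu0)^2)
  brute <- as.vector(pc1) * ((mu1 - mu0) / sw)
  got <- score_spectra(fit1, base)
  # identical up to the sign/scale-free ranking
  expect_equal(rank(got), rank(sign(cor(got, brute)) * brute))
  expect_equal(abs(cor(got, brute)), 1, tolerance = 1e-12)

  expect_error(fit_pcalda(base, rep(TRUE, n), p = 2), "both classes")
  expect_error(fit_pcalda(base, lab, p = 0), "p must")
})

test_that("shuffled labels give chance-level training AUC", {
  set.seed(9)
  n <- 500
  sp <- matrix(rnorm(n * 15), n, 15)
  lab <- sample(rep(c(TRUE, FALSE), each = n / 2))
  fit <- fit_pcalda(sp, lab, p = 5)
  auc <- roc_curve(score_spectra(fit, sp), lab)$auc
  expect_gte(auc, 0.5)   # training AUC is oriented upward by construction
  expect_lte(auc, 0.65)
})

test_that("Fisher direction agrees with MASS::lda up to scale", {
  skip_if_not_installed("MASS")
  set.seed(10)
  n <- 80
  sc <- matrix(rnorm(n * 4), n, 4)
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  sc[lab, ] <- sc[lab, ] + c(1, 0.5, 0, -0.3)
  fit <- fit_pcalda(sc, lab, p = 4)
  ld <- MASS::lda(sc, grouping = lab)
  my_dir <- fit$loadings %*% fit$w
  expect_equal(abs(cor(as.vector(my_dir), as.vector(ld$scaling))), 1,
               tolerance = 1e-6)
})

test_that("leave-one-map-out selection breaks ties to the smallest p and recovers the signal rank", {
  # two identical separable maps -> AUC 1 for every p, chosen p = 1
  set.seed(12)
  one <- matrix(rnorm(40 * 6), 40, 6)
  lab <- rep(c(TRUE, FALSE), each = 20)
  one[lab, 1] <- one[lab, 1] + 10
  maps <- list(list(spectra = one, labels = lab, map_id = "a"),
               list(spectra = one, labels = lab, map_id = "b"))
  sel <- select_pc_count(maps, max_p = 4)
  expect_equal(nrow(sel$p_table), 4)
  expect_true(all(sel$p_table$auc == 1))
  expect_equal(sel$chosen_p, 1L)

  # class signal confined to the first two PCs: chosen p concentrates in {2, 3}
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    mk <- function() {
      n <- 60
      l <- rep(c(TRUE, FALSE), each = n / 2)
      s <- cbind(matrix(rnorm(n, sd = 8)),             # dominant noise PC1
                 matrix(rnorm(n, sd = 4)),             # signal axis = PC2
                 matrix(rnorm(n * 6, sd = 0.5), n, 6))
      s[l, 2] <- s[l, 2] + 3
      list(spectra = s, labels = l, map_id = paste0("m", runif(1)))
    }
    sel2 <- select_pc_count(list(mk(), mk(), mk(), mk()), max_p = 6)
    if (sel2$chosen_p %in% 2:3) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("folds that lose a class are skipped with a warning", {
  set.seed(13)
  sp <- matrix(rnorm(30 * 5), 30, 5)
  all_t <- list(spectra = sp, labels = rep(TRUE, 30), map_id = "t")
  all_n <- list(spectra = sp, labels = rep(FALSE, 30), map_id = "n")
  mixed <- list(spectra = sp, labels = rep(c(TRUE, FALSE), 15), map_id = "m")
  # holding out the mixed map leaves a single-class training set; the one
  # usable fold then holds out only tumor pixels, so no AUC is computable
  expect_warning(
    expect_error(select_pc_count(list(all_t, mixed), max_p = 2),
                 "single class"),
    "lost a class")
  two_mixed <- list(mixed, list(spectra = sp,
                                labels = rep(c(TRUE, FALSE), 15),
                                map_id = "m2"), all_t)
  expect_warning(sel <- select_pc_count(two_mixed, max_p = 2), NA)
  expect_equal(sel$n_folds_used, 3L)
  expect_error(suppressWarnings(select_pc_count(list(all_t, all_n), max_p = 2)),
               "all folds skipped")
})

test_that("validation is deterministic, guards patient overlap, and reports degenerate labels", {
  set.seed(15)
  n <- 60
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  sp <- matrix(rnorm(n * 8), n, 8); sp[lab, 1] <- sp[lab, 1] + 2
  fit <- fit_pcalda(sp, lab, p = 2, map_ids = "m1", patient_ids = "P01")
  tm <- list(list(spectra = sp, labels = lab, map_id = "m2",
                  patient_id = "P09"))
  v1 <- validate_model(fit, tm)
  v2 <- validate_model(fit, tm)
  expect_identical(v1$scores, v2$scores)
  expect_identical(v1$scores, score_spectra(fit, sp))

  # all-non-tumor test map: scores computed, AUC undefined
  tn <- list(list(spectra = sp[1:10, ], labels = rep(FALSE, 10),
                  map_id = "m3", patient_id = "P08"))
  expect_true(is.na(validate_model(fit, tn)$auc))
  expect_length(validate_model(fit, tn)$scores, 10)

  # duplicate training patient in the test set: error
  bad <- list(list(spectra = sp, labels = lab, map_id = "m4",
                   patient_id = "P01"))
  expect_error(validate_model(fit, bad), "overlap")
})
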