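# CH-stretching region (2800-3100 1/cm) analysis: EMSC with a water
# interferent, Savitzky-Golay smoothing, PCA visualization and PCA-LDA
# classification with leave-one-map-out PC-count selection.

#' Restrict spectra to the CH-stretching analysis window
#'
#' @param spectra Numeric matrix (rows = spectra) on the full axis, or a
#'   single vector.
#' @param axis The matching [wavenumber_axis()].
#' @param window Window limits in 1/cm.
#' @return List with `axis` (window axis points) and `spectra` (matrix
#'   restricted to the window).
#' @export
restrict_window <- function(spectra, axis, window = c(2800, 3100)) {
  if (is.vector(spectra)) spectra <- matrix(spectra, 1)
  idx <- which(axis >= window[1] & axis <= window[2])
  if (length(idx) < 8) stop("window contains too few channels")
  list(axis = as.numeric(axis)[idx], spectra = spectra[, idx, drop = FALSE])
}

#' Build an EMSC model
#'
#' Extended multiplicative scatter correction: every spectrum `s` on the
#' window is modelled as
#' `s = a * 1 + (baseline polynomial) + b * m + sum_i c_i * g_i + e`,
#' where `m` is the reference spectrum (by default the mean of the supplied
#' analysis spectra) and the `g_i` are interferent spectra (here: a water
#' spectrum restricted to the window, so that varying water contributions
#' are removed and the CH-region analysis is independent of the water
#' signal). The corrected spectrum is `(s - a*1 - baseline - sum c_i g_i) / b`.
#'
#' @param spectra Matrix of analysis spectra on the window (rows = spectra),
#'   used to form the reference unless `reference` is given.
#' @param axis Window axis points.
#' @param interferents Matrix with one interferent spectrum per column (or a
#'   single vector), e.g. from [water_interferent()].
#' @param poly_order Baseline polynomial order inside the window (default 1:
#'   the global 3rd-order background was already removed).
#' @param reference Optional explicit reference spectrum.
#' @return An object of class `emsc_model`.
#' @export
emsc_model <- function(spectra, axis, interferents = NULL, poly_order = 1L,
                       reference = NULL) {
  if (is.vector(spectra)) spectra <- matrix(spectra, 1)
  stopifnot(ncol(spectra) == length(axis))
  m <- if (is.null(reference)) colMeans(spectra) else as.numeric(reference)
  G <- NULL
  if (!is.null(interferents)) {
    G <- as.matrix(interferents)
    stopifnot(nrow(G) == length(axis))
    # unit-norm columns for conditioning; coefficients are in those units
    G <- sweep(G, 2, sqrt(colSums(G^2)), "/")
  }
  t <- seq(-1, 1, length.out = length(axis))
  P <- sapply(0:poly_order, function(d) t^d)
  X <- cbind(P, m, G)
  if (qr(X)$rank < ncol(X))
    stop("EMSC design matrix is rank deficient: reference, baseline and ",
         "interferent columns must be linearly independent")
  structure(list(axis = as.numeric(axis), reference = m, interferents = G,
                 poly_order = as.integer(poly_order), design = X,
                 qr = qr(X), n_baseline = ncol(P)),
            class = "emsc_model")
}

#' Apply an EMSC correction
#'
#' Least-squares fit of the EMSC design to the spectrum, followed by
#' removal of the baseline and interferent parts and division by the
#' reference coefficient `b`. The output is invariant to multiplicative
#' scaling of the input and to addition of any multiple of an interferent.
#'
#' @param spectrum Intensity vector on the model window (or a matrix with
#'   one spectrum per row; see `emsc_correct_matrix` for the flagged bulk
#'   version).
#' @param model An [emsc_model()].
#' @return The corrected spectrum. Errors when `|b| < 1e-8` (degenerate
#'   spectrum carrying no reference signal).
#' @export
emsc_correct <- function(spectrum, model) {
  stopifnot(inherits(model, "emsc_model"))
  res <- emsc_correct_matrix(matrix(spectrum, 1), model)
  if (!res$valid[1])
    stop("degenerate spectrum: EMSC reference coefficient |b| < 1e-8")
  as.vector(res$corrected)
}

#' @rdname emsc_correct
#' @param spectra Matrix, one spectrum per row.
#' @return `emsc_correct_matrix`: list with `corrected` (matrix, rows of
#'   degenerate spectra set to `NA`), `valid` (logical), `b` (reference
#'   coefficients).
#' @export
emsc_correct_matrix <- function(spectra, model) {
  stopifnot(inherits(model, "emsc_model"),
            ncol(spectra) == length(model$axis))
  coef <- qr.coef(model$qr, t(spectra))     # k x n
  nb <- model$n_baseline
  b <- unname(coef[nb + 1, ])
  nuis_idx <- setdiff(seq_len(nrow(coef)), nb + 1)
  nuisance <- model$design[, nuis_idx, drop = FALSE] %*%
    coef[nuis_idx, , drop = FALSE]          # chan x n
  corrected <- (t(spectra) - nuisance) / rep(b, each = length(model$axis))
  valid <- abs(b) >= 1e-8
  corrected <- t(corrected)
  corrected[!valid, ] <- NA_real_
  list(corrected = corrected, valid = valid, b = b)
}

#' Savitzky-Golay smoothing
#'
#' Order-3, window-11 Savitzky-Golay filter by default (exactly reproduces
#' any cubic polynomial). Edge channels are handled by the polynomial fit
#' on the available one-sided window, as in [signal::sgolayfilt()].
#'
#' @param spectrum Intensity vector (or matrix, one spectrum per row).
#' @param order Polynomial order.
#' @param window Window length (odd, > order).
#' @return The smoothed spectrum / matrix.
#' @export
sg_filter <- function(spectrum, order = 3L, window = 11L) {
  if (window %% 2L == 0L || window <= order)
    stop("window must be odd and greater than order")
  if (is.matrix(spectrum)) {
    if (ncol(spectrum) < window) stop("window exceeds spectrum length")
    S <- sg_matrix(ncol(spectrum), order, window)
    return(spectrum %*% t(S))
  }
  if (length(spectrum) < window) stop("window exceeds spectrum length")
  as.vector(signal::sgolayfilt(spectrum, p = order, n = window))
}

# full L x L smoothing operator replicating sgolayfilt (including its
# polynomial edge handling), for vectorized filtering of spectra matrices
sg_matrix <- function(L, order, window) {
  F <- unclass(signal::sgolay(p = order, n = window))
  k <- (window - 1L) %/% 2L
  S <- matrix(0, L, L)
  for (i in seq_len(k)) S[i, 1:window] <- F[i, ]
  for (i in (k + 1):(L - k)) S[i, (i - k):(i + k)] <- F[k + 1L, ]
  for (i in seq_len(k)) S[L - k + i, (L - window + 1L):L] <- F[k + 1L + i, ]
  S
}

#' PCA false-colour map of one spectral map
#'
#' Per-map PCA of the corrected CH-window spectra; the scores on the first
#' three principal components are min-max scaled to \[0, 1\] and used as
#' the red, green and blue channels. Invalid pixels are rendered black; a
#' zero-variance component gives a flat 0.5 channel.
#'
#' @param spectra Matrix of corrected spectra for the valid pixels of one
#'   map (rows in row-major pixel order of `which_valid`).
#' @param valid Logical grid marking which pixels the rows belong to.
#' @return Numeric array `nrow x ncol x 3` with values in \[0, 1\].
#' @export
pca_rgb_map <- function(spectra, valid) {
  n <- sum(valid)
  if (nrow(spectra) != n) stop("one spectrum per valid pixel required")
  if (n < 3) stop("at least 3 valid spectra required for a PCA map")
  pr <- stats::prcomp(spectra, center = TRUE, scale. = FALSE)
  img <- array(0, c(nrow(valid), ncol(valid), 3))
  ord <- which(t(valid))  # row-major positions of valid pixels
  for (ch in 1:3) {
    if (ncol(pr$x) >= ch && pr$sdev[ch] > 1e-12) {
      sc <- pr$x[, ch]
      sc <- (sc - min(sc)) / (max(sc) - min(sc))
    } else sc <- rep(0.5, n)
    plane <- matrix(0, ncol(valid), nrow(valid))  # transposed for row-major fill
    plane[ord] <- sc
    img[, , ch] <- t(plane)
  }
  img
}

# Fisher LDA on score matrices: returns the discriminant direction oriented
# so the positive class scores higher, plus the ridge flag
fisher_lda <- function(scores, positive) {
  mu1 <- colMeans(scores[positive, , drop = FALSE])
  mu0 <- colMeans(scores[!positive, , drop = FALSE])
  c1 <- sweep(scores[positive, , drop = FALSE], 2, mu1)
  c0 <- sweep(scores[!positive, , drop = FALSE], 2, mu0)
  Sw <- crossprod(c1) + crossprod(c0)
  dmu <- mu1 - mu0
  w <- tryCatch(solve(Sw, dmu), error = function(e) {
    ridge <- 1e-8 * sum(diag(Sw)) / ncol(Sw)
    solve(Sw + diag(ridge, ncol(Sw)), dmu)
  })
  if (sum(w * dmu) < 0) w <- -w   # tumor scores higher by construction
  w
}

#' Fit a PCA-LDA tumor classifier
#'
#' PCA (mean-centred, unscaled) on the pooled training spectra, followed by
#' Fisher linear discriminant analysis on the scores of the first `p`
#' components: the discriminant direction maximizes the ratio of
#' between-group to within-group variance, `w` proportional to
#' `Sw^-1 (mu_tumor - mu_nontumor)`. The scalar tumor score of a spectrum
#' is its projection onto `w`, oriented so tumor scores are higher; the
#' stored decision threshold is the Youden point of the training ROC.
#' A singular within-class scatter is regularized with a ridge of
#' `1e-8 * trace(Sw) / p`.
#'
#' @param spectra Training matrix (rows = corrected, filtered spectra).
#' @param labels Logical (or `"TUMOR"`-containing character) vector; `TRUE`
#'   = tumor.
#' @param p Number of leading principal components to use.
#' @param map_ids,patient_ids Optional training metadata (stored for the
#'   independence guard in [validate_model()]).
#' @return An object of class `pcalda_model`.
#' @export
fit_pcalda <- function(spectra, labels, p, map_ids = NULL,
                       patient_ids = NULL) {
  positive <- if (is.character(labels)) labels == "TUMOR" else as.logical(labels)
  if (!any(positive) || all(positive))
    stop("both classes must be present in the training data")
  if (p < 1 || p > min(nrow(spectra) - 2, ncol(spectra)))
    stop("p must lie in [1, min(n - 2, channels)]")
  pr <- stats::prcomp(spectra, center = TRUE, scale. = FALSE, rank. = p)
  scores <- pr$x[, seq_len(p), drop = FALSE]
  w <- fisher_lda(scores, positive)
  s_train <- as.vector(scores %*% w)
  thr <- youden_point(roc_curve(s_train, positive))$threshold
  structure(list(center = pr$center,
                 loadings = pr$rotation[, seq_len(p), drop = FALSE],
                 p = as.integer(p), w = as.numeric(w), threshold = thr,
                 train_maps = unique(map_ids),
                 train_patients = unique(patient_ids)),
            class = "pcalda_model")
}

#' Score spectra with a fitted PCA-LDA model
#'
#' @param model A `pcalda_model`.
#' @param spectra Matrix of corrected, filtered spectra on the same window.
#' @return Numeric vector of tumor scores (higher = more tumor-like).
#' @export
score_spectra <- function(model, spectra) {
  stopifnot(inherits(model, "pcalda_model"))
  if (is.vector(spectra)) spectra <- matrix(spectra, 1)
  sc <- sweep(spectra, 2, model$center) %*% model$loadings
  as.vector(sc %*% model$w)
}

#' Select the PC count by leave-one-map-out validation
#'
#' For every candidate `p` in `1..max_p` and every map, a PCA-LDA model is
#' fitted on the remaining maps and scores the held-out map; all held-out
#' scores are pooled and the pooled ROC AUC is computed. The chosen `p`
#' maximizes the pooled AUC, with ties broken towards the smallest `p`
#' (parsimony). Folds whose training data lose a class are skipped with a
#' warning.
#'
#' @param model_maps List of entries, each `list(spectra, labels, map_id)`.
#' @param max_p Largest candidate PC count.
#' @return An object of class `model_selection`: `p_table` (data frame
#'   `p`, `auc`), `chosen_p`, `pooled` (per-`p` list of pooled held-out
#'   scores and labels), `n_folds_used`.
#' @export
select_pc_count <- function(model_maps, max_p = 20L) {
  if (length(model_maps) < 2) stop("at least 2 maps required")
  max_p <- as.integer(max_p)
  pooled_scores <- rep(list(numeric(0)), max_p)
  pooled_labels <- rep(list(logical(0)), max_p)
  used <- 0L
  for (hold in seq_along(model_maps)) {
    train <- do.call(rbind, lapply(model_maps[-hold], `[[`, "spectra"))
    tlab <- unlist(lapply(model_maps[-hold], `[[`, "labels"))
    positive <- if (is.character(tlab)) tlab == "TUMOR" else as.logical(tlab)
    if (!any(positive) || all(positive)) {
      warning("fold ", hold, " skipped: training set lost a class")
      next
    }
    if (max_p > min(nrow(train) - 2, ncol(train)))
      stop("max_p exceeds the feasible PC count for fold ", hold)
    pr <- stats::prcomp(train, center = TRUE, scale. = FALSE, rank. = max_p)
    tr_scores <- pr$x[, seq_len(max_p), drop = FALSE]
    ho <- model_maps[[hold]]
    ho_scores <- sweep(ho$spectra, 2, pr$center) %*%
      pr$rotation[, seq_len(max_p), drop = FALSE]
    ho_pos <- if (is.character(ho$labels)) ho$labels == "TUMOR"
              else as.logical(ho$labels)
    for (p in seq_len(max_p)) {
      w <- fisher_lda(tr_scores[, seq_len(p), drop = FALSE], positive)
      s <- as.vector(ho_scores[, seq_len(p), drop = FALSE] %*% w)
      pooled_scores[[p]] <- c(pooled_scores[[p]], s)
      pooled_labels[[p]] <- c(pooled_labels[[p]], ho_pos)
    }
    used <- used + 1L
  }
  if (used == 0L) stop("all folds skipped: no usable training split")
  auc <- vapply(seq_len(max_p), function(p) {
    lab <- pooled_labels[[p]]
    if (!any(lab) || all(lab)) return(NA_real_)
    roc_curve(pooled_scores[[p]], lab)$auc
  }, 0)
  if (all(is.na(auc)))
    stop("pooled held-out scores contain a single class; AUC undefined")
  chosen <- which(auc == max(auc, na.rm = TRUE))[1]
  structure(list(p_table = data.frame(p = seq_len(max_p), auc = auc),
                 chosen_p = as.integer(chosen),
                 pooled = list(scores = pooled_scores, labels = pooled_labels),
                 n_folds_used = used),
            class = "model_selection")
}

#' Validate a PCA-LDA model on an independent test set
#'
#' Scores every spectrum of the test maps with the fitted model, without
#' any refitting. Errors if a test patient also appears among the model's
#' training patients (guards the independence of the validation).
#'
#' @param model A `pcalda_model` carrying `train_patients`.
#' @param test_maps List of entries `list(spectra, labels, map_id,
#'   patient_id)`.
#' @return List: `scores` (pooled), `labels` (pooled logical), `per_map`
#'   (list of per-map score vectors), `auc` (`NA` when only one class is
#'   present in the test labels).
#' @export
validate_model <- function(model, test_maps) {
  stopifnot(inherits(model, "pcalda_model"))
  test_pat <- unique(unlist(lapply(test_maps, `[[`, "patient_id")))
  overlap <- intersect(model$train_patients, test_pat)
  if (length(overlap))
    stop("test patients overlap the training set: ",
         paste(overlap, collapse = ", "))
  per_map <- lapply(test_maps, function(e) score_spectra(model, e$spectra))
  names(per_map) <- vapply(test_maps, function(e)
    if (is.null(e$map_id)) "" else e$map_id, "")
  scores <- unlist(per_map, use.names = FALSE)
  lab <- unlist(lapply(test_maps, function(e)
    if (is.character(e$labels)) e$labels == "TUMOR" else as.logical(e$labels)))
  auc <- if (any(lab) && !all(lab)) roc_curve(scores, lab)$auc else NA_real_
  list(scores = scores, labels = lab, per_map = per_map, auc = auc)
}
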