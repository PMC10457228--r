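# Spectral preprocessing: cosmic-ray removal, iterative polynomial
# autofluorescence subtraction, intensity-based quality gate.

#' Remove cosmic-ray spikes from a spectrum
#'
#' Detects isolated positive spikes (at most `max_width` channels wide)
#' exceeding `k` robust deviations above a rolling median and replaces them
#' by linear interpolation of the neighbouring channels. Wider
#' above-threshold features (real bands) are left untouched, so a
#' spike-free spectrum is a fixed point and the operation is idempotent.
#'
#' @param spectrum Finite numeric intensity vector.
#' @param k MAD multiplier of the detection threshold.
#' @param window Rolling-median window (odd).
#' @param max_width Maximum spike width in channels.
#' @return The corrected spectrum; all non-spike channels are returned
#'   exactly unchanged.
#' @export
remove_cosmic_rays <- function(spectrum, k = 8, window = 9L, max_width = 2L) {
  if (any(!is.finite(spectrum))) stop("spectrum must be finite")
  n <- length(spectrum)
  if (n < window) return(spectrum)
  med <- stats::runmed(spectrum, window, endrule = "median")
  resid <- spectrum - med
  scale <- stats::mad(resid)
  cand <- resid > k * scale  # with scale 0 only strictly positive residuals
  if (!any(cand)) return(spectrum)
  out <- spectrum
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths <= max_width)) {
    a <- starts[i]; b <- ends[i]
    left <- a - 1L; right <- b + 1L
    if (left >= 1L && right <= n) {
      out[a:b] <- out[left] + (out[right] - out[left]) *
        (seq(a, b) - left) / (right - left)
    } else if (left >= 1L) {
      out[a:b] <- out[left]          # one-sided at the upper boundary
    } else if (right <= n) {
      out[a:b] <- out[right]         # one-sided at the lower boundary
    }
  }
  out
}

# orthonormal polynomial projector for the baseline fit, built once per axis
baseline_basis <- function(axis, degree) {
  X <- cbind(1, stats::poly(as.numeric(axis), degree))
  qr.Q(qr(X))
}

#' Subtract the autofluorescence background
#'
#' Estimates the smooth fluorescence baseline as a polynomial of degree
#' `degree` (default 3) by iterative peak clipping: after each fit, data
#' points above the fitted curve are clamped to it, so over the iterations
#' the polynomial settles under the Raman bands and hugs the baseline.
#' The fit runs on the full high-wavenumber range.
#'
#' @param spectrum Spike-free intensity vector.
#' @param axis The matching [wavenumber_axis()].
#' @param degree Polynomial degree.
#' @param iterations Maximum clipping iterations.
#' @param tol Convergence tolerance on the change of the fitted-coefficient
#'   vector, relative to the spectrum scale.
#' @return The background-subtracted spectrum (small negatives permitted).
#' @export
subtract_background <- function(spectrum, axis, degree = 3L,
                                iterations = 20L, tol = 1e-8) {
  if (length(spectrum) < 8) stop("fit error: fewer than 8 channels")
  stopifnot(length(spectrum) == length(axis))
  Q <- baseline_basis(axis, degree)
  as.vector(subtract_background_matrix(matrix(spectrum, 1), Q,
                                       iterations, tol))
}

# vectorized core: Y is n_spectra x n_channels, Q the orthonormal basis
subtract_background_matrix <- function(Y, Q, iterations = 20L, tol = 1e-8) {
  Ycur <- Y
  coef_prev <- NULL
  fit <- NULL
  scale <- max(abs(Y), 1e-300)
  for (it in seq_len(iterations)) {
    G <- Ycur %*% Q                     # coefficients in the orthonormal basis
    fit <- G %*% t(Q)
    if (!is.null(coef_prev) && max(abs(G - coef_prev)) < tol * scale) break
    coef_prev <- G
    Ycur <- pmin(Ycur, fit)
  }
  Y - fit
}

#' Quality-gate low-signal pixels
#'
#' For every valid pixel the mean intensity over the quality band
#' (default 2700-3100 1/cm) is taken as the signal-quality measure; pixels
#' whose measure falls strictly below `quality_gate_fraction` times the
#' overall mean (the mean of the per-pixel measures across all valid
#' pixels of the dataset, or of each map when
#' `quality_gate_scope = "map"`) are flagged invalid.
#'
#' @param maps A single `spectral_map` or a list of them.
#' @param cfg An [analysis_config()].
#' @return List with `maps` (same shape as the input, gated) and `report`
#'   (data frame: `map_id`, `n_total`, `n_valid_before`,
#'   `n_excluded_quality`, `mean_intensity`), plus attribute
#'   `overall_mean`.
#' @export
quality_gate <- function(maps, cfg = analysis_config()) {
  single <- inherits(maps, "spectral_map")
  if (single) maps <- list(maps)
  if (!length(maps)) stop("empty map set")
  means <- lapply(maps, function(m) {
    idx <- which(m$axis >= cfg$quality_band[1] & m$axis <= cfg$quality_band[2])
    if (!length(idx)) stop("quality band outside the axis range")
    rowMeans(m$spectra[, idx, drop = FALSE])
  })
  valid <- lapply(maps, function(m) as.vector(t(m$pixel_valid)))
  if (!any(unlist(valid))) stop("empty map: no valid pixels to gate")

  overall_all <- mean(unlist(mapply(function(mu, v) mu[v], means, valid,
                                    SIMPLIFY = FALSE)))
  report <- data.frame(map_id = character(0), n_total = integer(0),
                       n_valid_before = integer(0),
                       n_excluded_quality = integer(0),
                       mean_intensity = numeric(0))
  for (i in seq_along(maps)) {
    m <- maps[[i]]; mu <- means[[i]]; v <- valid[[i]]
    overall <- if (cfg$quality_gate_scope == "map") mean(mu[v]) else overall_all
    drop <- v & (mu < cfg$quality_gate_fraction * overall)
    v_new <- v & !drop
    m$pixel_valid <- matrix(v_new, m$nrow, m$ncol, byrow = TRUE)
    maps[[i]] <- m
    report <- rbind(report, data.frame(
      map_id = m$map_id, n_total = length(mu), n_valid_before = sum(v),
      n_excluded_quality = sum(drop), mean_intensity = mean(mu[v])))
  }
  attr(report, "overall_mean") <- overall_all
  list(maps = if (single) maps[[1]] else maps, report = report)
}

#' Preprocess a cohort of maps
#'
#' Runs the full preprocessing chain on every map: cosmic-ray removal,
#' autofluorescence background subtraction, then the intensity quality gate
#' (computed after background subtraction by default, before it with
#' `quality_gate_stage = "pre"`; the overall mean is dataset-wide by
#' default).
#'
#' @param cohort A `raman_cohort` (or any list of entries with `$map`).
#' @param cfg An [analysis_config()].
#' @return The cohort with preprocessed maps, plus attribute `report`
#'   (the [quality_gate()] report).
#' @export
preprocess_cohort <- function(cohort, cfg = analysis_config()) {
  entries <- cohort
  axis <- entries[[1]]$map$axis
  Q <- baseline_basis(axis, cfg$background_degree)
  pre_gate_maps <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    m <- entries[[i]]$map
    for (px in seq_len(nrow(m$spectra)))
      m$spectra[px, ] <- remove_cosmic_rays(m$spectra[px, ],
                                            k = cfg$cosmic_k,
                                            window = cfg$cosmic_window)
    pre_gate_maps[[i]] <- m
    m$spectra <- subtract_background_matrix(m$spectra, Q)
    entries[[i]]$map <- m
  }
  gate_input <- if (cfg$quality_gate_stage == "pre") pre_gate_maps
                else lapply(entries, `[[`, "map")
  gated <- quality_gate(gate_input, cfg)
  for (i in seq_along(entries))
    entries[[i]]$map$pixel_valid <- gated$maps[[i]]$pixel_valid
  attr(entries, "report") <- gated$report
  class(entries) <- class(cohort)
  for (a in c("model_patients", "test_patients", "seed"))
    attr(entries, a) <- attr(cohort, a)
  entries
}
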