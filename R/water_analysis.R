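# Per-pixel water-concentration analysis: band-ratio estimator, outlier
# rule, 3x3 map smoothing, annotation grouping, tumor vs non-tumor test.

#' Estimate the tissue water fraction of one spectrum
#'
#' Band-ratio water estimator: the OH-stretching band area (default
#' 3350-3550 1/cm, trapezoidal on the axis) is divided by the
#' CH-stretching band area (default 2910-2966 1/cm) to give the ratio
#' `rho`, which is mapped to a mass fraction `w = rho / (rho + R)` with
#' the instrument calibration constant `R` and clipped to \[0, 1\].
#'
#' @param spectrum Preprocessed (background-subtracted) intensity vector.
#' @param axis The matching [wavenumber_axis()].
#' @param cfg An [analysis_config()] supplying the band limits and `R`.
#' @return Water fraction in \[0, 1\], or `NA_real_` when the CH band area
#'   is non-positive (invalid estimate; flag the pixel).
#' @export
estimate_water <- function(spectrum, axis, cfg = analysis_config()) {
  ch <- band_area(axis, spectrum, cfg$ch_band)
  if (!is.finite(ch) || ch <= 0) return(NA_real_)
  oh <- band_area(axis, spectrum, cfg$oh_band)
  rho <- max(oh / ch, 0)
  min(max(rho / (rho + cfg$water_cal_r), 0), 1)
}

#' Compute a per-pixel water map
#'
#' Applies [estimate_water()] to every valid pixel of a map. Pixels with an
#' invalid estimate (non-positive CH band area) are flagged invalid.
#'
#' @param map A preprocessed `spectral_map`.
#' @param cfg An [analysis_config()].
#' @return An object of class `water_map`: `w` (numeric grid, `NA` where
#'   invalid), `valid` (logical grid), `smoothed` (filled by
#'   [smooth_map()]), `n_discarded_outlier`, `map_id`.
#' @export
compute_water_map <- function(map, cfg = analysis_config()) {
  w <- matrix(NA_real_, map$nrow, map$ncol)
  valid <- map$pixel_valid
  for (r in seq_len(map$nrow)) for (c in seq_len(map$ncol)) {
    if (!valid[r, c]) next
    wi <- estimate_water(map$spectra[pixel_index(map, r, c), ], map$axis, cfg)
    if (is.na(wi)) valid[r, c] <- FALSE else w[r, c] <- wi
  }
  structure(list(w = w, valid = valid, smoothed = NULL,
                 n_discarded_outlier = NA_integer_, map_id = map$map_id),
            class = "water_map")
}

#' Discard physically implausible water fractions
#'
#' Pixels with water fraction strictly above the ceiling (default 0.88)
#' are considered outliers and invalidated; a fraction of exactly the
#' ceiling is retained.
#'
#' @param wm A `water_map`.
#' @param cfg An [analysis_config()].
#' @return The `water_map` with outliers invalidated and
#'   `n_discarded_outlier` set.
#' @export
apply_outlier_rule <- function(wm, cfg = analysis_config()) {
  out <- wm$valid & !is.na(wm$w) & wm$w > cfg$water_outlier_max
  wm$valid[out] <- FALSE
  wm$w[out] <- NA_real_
  wm$n_discarded_outlier <- sum(out)
  wm
}

#' Smooth a water map with a 3x3 average filter
#'
#' Each valid pixel is replaced by the mean of the valid pixels in its
#' 3x3 neighbourhood (including itself); invalid neighbours are omitted
#' from the mean, edge pixels use the in-bounds neighbourhood, and invalid
#' pixels are never imputed — they stay invalid (rendered black on maps).
#' Smoothing is for display and noise reduction; group statistics use the
#' raw estimates.
#'
#' @param wm A `water_map`.
#' @return The `water_map` with `smoothed` filled in.
#' @export
smooth_map <- function(wm) {
  nr <- nrow(wm$w); nc <- ncol(wm$w)
  sm <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!wm$valid[r, c]) next
    rs <- max(1, r - 1):min(nr, r + 1)
    cs <- max(1, c - 1):min(nc, c + 1)
    nb_w <- wm$w[rs, cs]
    nb_v <- wm$valid[rs, cs]
    sm[r, c] <- mean(nb_w[nb_v])
  }
  wm$smoothed <- sm
  wm
}

#' Split water fractions into tumor and non-cancerous groups
#'
#' Selects pixels with an unambiguous tissue annotation (neither
#' `AMBIGUOUS` nor `BACKGROUND`) and a valid water estimate, and splits
#' them into the tumor group and the pooled non-cancerous group; per-type
#' subsets are retained for histograms.
#'
#' @param wm A `water_map`.
#' @param mask The matching [annotation_mask()].
#' @return An object of class `grouped_water`: `tumor`, `noncancer`
#'   (numeric vectors), `per_type` (named list).
#' @export
collect_groups <- function(wm, mask) {
  stopifnot(all(dim(mask) == dim(wm$w)))
  usable <- wm$valid & !is.na(wm$w) &
    matrix(unclass(mask) %in% ANALYSIS_LABELS, nrow(wm$w), ncol(wm$w))
  if (!any(usable))
    stop("no valid pixels with unambiguous tissue annotation")
  lab <- unclass(mask)[usable]
  w <- wm$w[usable]
  per_type <- split(w, factor(lab, levels = ANALYSIS_LABELS), drop = TRUE)
  structure(list(tumor = w[lab == "TUMOR"], noncancer = w[lab != "TUMOR"],
                 per_type = per_type),
            class = "grouped_water")
}

# pool grouped_water objects across maps
pool_groups <- function(group_list) {
  per_type <- list()
  for (g in group_list)
    for (t in names(g$per_type))
      per_type[[t]] <- c(per_type[[t]], g$per_type[[t]])
  structure(list(tumor = unlist(lapply(group_list, `[[`, "tumor")),
                 noncancer = unlist(lapply(group_list, `[[`, "noncancer")),
                 per_type = per_type),
            class = "grouped_water")
}

#' Compare tumor and non-cancerous water distributions
#'
#' Two-sided Wilcoxon rank-sum test (exact enumeration when both groups
#' have at most 10 tie-free observations, otherwise the normal
#' approximation with the tie-corrected variance) plus the area under the
#' ROC curve with the water fraction as the score and tumor as the
#' positive class.
#'
#' @param groups A `grouped_water` from [collect_groups()].
#' @return List: `p_value`, `auc`, `n_tumor`, `n_noncancer`,
#'   `mean_tumor`, `mean_noncancer`, `sd_tumor`, `sd_noncancer`.
#' @export
compare_water <- function(groups) {
  x <- groups$tumor; y <- groups$noncancer
  if (!length(x) || !length(y))
    stop("both groups must be non-empty for the comparison")
  all_tied <- length(unique(c(x, y))) == 1
  if (all_tied) {
    p <- 1; auc <- 0.5
  } else {
    ties <- any(duplicated(c(x, y)))
    exact <- length(x) <= 10 && length(y) <= 10 && !ties
    p <- stats::wilcox.test(x, y, exact = exact, correct = FALSE)$p.value
    auc <- roc_curve(c(x, y),
                     c(rep(TRUE, length(x)), rep(FALSE, length(y))))$auc
  }
  list(p_value = p, auc = auc, n_tumor = length(x), n_noncancer = length(y),
       mean_tumor = mean(x), mean_noncancer = mean(y),
       sd_tumor = stats::sd(x), sd_noncancer = stats::sd(y))
}

#' Plot a water map
#'
#' Renders the (smoothed, if available) water-fraction grid as an image;
#' invalid pixels are black.
#'
#' @param x A `water_map`.
#' @param smoothed Use the smoothed grid when available.
#' @param ... Passed to [graphics::image()].
#' @export
plot.water_map <- function(x, smoothed = TRUE, ...) {
  g <- if (smoothed && !is.null(x$smoothed)) x$smoothed else x$w
  z <- t(g[rev(seq_len(nrow(g))), , drop = FALSE])
  pal <- grDevices::hcl.colors(64, "Blues 3", rev = TRUE)
  graphics::image(z, col = pal, axes = FALSE, asp = nrow(g) / ncol(g),
                  main = paste("water map", x$map_id), ...)
  invisible(x)
}
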