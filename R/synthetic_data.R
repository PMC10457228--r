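# Synthetic hyperspectral tissue maps.
#
# Forward model per pixel:
#   spectrum = A * [ (1 - w) * P_tissue + w * W ] + background + shot noise
# where P_tissue is the tissue CH-stretching profile (supported on
# [2800, 3100] 1/cm), W the broad OH water band, w the pixel water fraction
# and A an amplitude that varies pixel to pixel (the multiplicative scatter
# EMSC has to remove).
#
# Both P and W are normalized so that their quantification-band areas are
# equal (P over the CH band [2910, 2966], W over the OH band [3350, 3550]),
# and W is tapered to exactly zero below the CH quantification band. The
# band ratio rho = OH/CH then equals w/(1-w) for every tissue, so the
# band-ratio water estimator with calibration constant R = 1 recovers w
# exactly in the noise-free limit — the generator defines the calibration,
# real instruments must supply their own R.

gauss_mix <- function(axis, centers, sigmas, weights) {
  y <- numeric(length(axis))
  for (i in seq_along(centers))
    y <- y + weights[i] * stats::dnorm(axis, centers[i], sigmas[i])
  y
}

smoothstep <- function(x, a, b) {
  t <- pmin(pmax((x - a) / (b - a), 0), 1)
  t * t * (3 - 2 * t)
}

# piecewise rescaling so the quantification-band trapezoid area is exactly
# `beta` and the total area stays 1
normalize_band_share <- function(axis, y, band, beta) {
  inb <- axis >= band[1] & axis <= band[2]
  a_in <- band_area(axis, y, band)
  a_tot <- band_area(axis, y, range(axis))
  a_out <- a_tot - a_in
  if (a_in <= 0 || a_out <= 0) stop("profile has no mass in/outside the band")
  y[inb] <- y[inb] * beta / a_in
  y[!inb] <- y[!inb] * (1 - beta) / a_out
  y
}

#' Tissue CH-stretching profiles and water-band model
#'
#' Builds the per-tissue spectral building blocks used by the map
#' generator: a unit-area CH-stretching profile per tissue type (a mixture
#' of 3-5 Gaussian bands around the lipid/protein CH stretches at
#' 2850/2885/2930/2960/3010 1/cm, zero outside \[2800, 3100\]), a broad OH
#' water band (Gaussian, centre 3400 1/cm, FWHM 260 1/cm, tapered to zero
#' below 3080 1/cm), and per-tissue water-fraction distributions.
#'
#' `delta` scales every tissue's deviation from the shared base profile and
#' is calibrated in L2 distance between unit-area profiles: at `delta = 0`
#' all tissues share one CH profile (the null case); the distance between
#' the tumor profile and non-cancerous profile `t` grows proportionally to
#' `delta`, with type-specific relative magnitudes ordered so that necrotic
#' tissue and gland resemble tumor most and muscle least.
#'
#' Water-fraction distributions are highly overlapping by default (means
#' 0.72-0.765, sd 0.045), emulating tissue in which every structure sits
#' near 75% water and water content alone barely discriminates.
#'
#' @param axis A [wavenumber_axis()].
#' @param delta CH effect size (L2 distance scale between unit-area
#'   profiles); the default 0.05 gives moderate class separation under the
#'   default noise level (pooled held-out AUC near 0.9).
#' @param water_means,water_sds Named numeric vectors (one entry per
#'   analysis tissue label) of water-fraction means and standard deviations.
#' @param beta Shared quantification-band area fraction (internal
#'   calibration constant of the generator).
#' @return An object of class `tissue_profiles` with elements `axis`,
#'   `profiles` (tissue x channel matrix), `water_band`, `water_params`,
#'   `delta`, and `cal_r` (the calibration constant, 1, for which the
#'   band-ratio estimator is exact).
#' @export
tissue_profiles <- function(axis = default_axis(),
                            delta = 0.05,
                            water_means = c(TUMOR = 0.765, CONNECTIVE = 0.75,
                                            GLAND = 0.755, CARTILAGE = 0.72,
                                            MUSCLE = 0.745, NECROSIS = 0.765),
                            water_sds = c(TUMOR = 0.045, CONNECTIVE = 0.045,
                                          GLAND = 0.045, CARTILAGE = 0.045,
                                          MUSCLE = 0.045, NECROSIS = 0.045),
                            beta = 0.35) {
  axis <- if (inherits(axis, "wavenumber_axis")) axis else wavenumber_axis(axis)
  if (delta < 0) stop("delta must be >= 0")
  stopifnot(all(ANALYSIS_LABELS %in% names(water_means)),
            all(ANALYSIS_LABELS %in% names(water_sds)))
  ch_window <- c(2800, 3100)
  ch_band <- c(2910, 2966)
  oh_band <- c(3350, 3550)
  in_window <- axis >= ch_window[1] & axis <= ch_window[2]

  base <- gauss_mix(axis,
                    centers = c(2850, 2885, 2930, 2960, 3010),
                    sigmas  = c(18, 16, 20, 14, 16),
                    weights = c(0.80, 0.55, 1.00, 0.40, 0.25))
  base[!in_window] <- 0

  # unit-L2, area-neutral perturbation directions (difference of Gaussians)
  perturb <- function(c1, s1, c2, s2) {
    u <- gauss_mix(axis, c(c1, c2), c(s1, s2), c(1, -1))
    u[!in_window] <- 0
    u / sqrt(sum(u^2))
  }
  dirs <- list(
    TUMOR      = perturb(2930, 15, 2852, 18),
    NECROSIS   = perturb(2925, 22, 2958, 14),
    GLAND      = perturb(2848, 16, 2932, 22),
    CONNECTIVE = perturb(2940, 18, 2878, 16),
    CARTILAGE  = perturb(2890, 14, 3005, 20),
    MUSCLE     = perturb(2962, 13, 2845, 20))
  # relative deviation magnitudes: necrosis/gland most tumor-like, muscle least
  mags <- c(TUMOR = 1.0, NECROSIS = 0.30, GLAND = 0.40,
            CONNECTIVE = 0.80, CARTILAGE = 1.00, MUSCLE = 1.30)

  # scale directions so that delta is an L2 distance between *unit-area*
  # profiles: base has unit area, so apply delta directly to the density
  base_area <- band_area(axis, base, range(axis))
  base <- base / base_area
  profiles <- matrix(0, length(ANALYSIS_LABELS), length(axis),
                     dimnames = list(ANALYSIS_LABELS, NULL))
  l2_scale <- sqrt(sum(base^2))
  for (t in ANALYSIS_LABELS) {
    p <- base + delta * mags[[t]] * l2_scale * dirs[[t]]
    p[p < 0] <- 0
    p <- p / band_area(axis, p, range(axis))
    profiles[t, ] <- normalize_band_share(axis, p, ch_band, beta)
  }

  w_band <- stats::dnorm(axis, 3400, 260 / (2 * sqrt(2 * log(2)))) *
    smoothstep(axis, 2990, 3080)
  w_band <- w_band * beta / band_area(axis, w_band, oh_band)

  structure(list(axis = axis, profiles = profiles, water_band = w_band,
                 water_params = data.frame(tissue = ANALYSIS_LABELS,
                                           mean = water_means[ANALYSIS_LABELS],
                                           sd = water_sds[ANALYSIS_LABELS],
                                           row.names = NULL),
                 delta = delta, beta = beta, cal_r = 1,
                 ch_window = ch_window, ch_band = ch_band, oh_band = oh_band),
            class = "tissue_profiles")
}

#' Water interferent spectrum on the CH analysis window
#'
#' The generator's pure-water OH band restricted to the CH-stretching
#' window, for use as the EMSC interferent. For real instruments a measured
#' water spectrum should be supplied instead.
#'
#' @param profiles A [tissue_profiles()] object.
#' @param window Window limits (1/cm).
#' @return List with `axis` (window axis points) and `spectrum`.
#' @export
water_interferent <- function(profiles, window = profiles$ch_window) {
  idx <- which(profiles$axis >= window[1] & profiles$axis <= window[2])
  list(axis = profiles$axis[idx], spectrum = profiles$water_band[idx])
}

#' Scene specification for synthetic maps
#'
#' Describes one map acquisition: grid geometry, tissue classes, noise and
#' artefact levels. Tissue regions are random smoothed-threshold blobs
#' unless an explicit `label_grid` is supplied (for deterministic tests).
#'
#' @param nrow,ncol Grid dimensions.
#' @param step_size Grid step in micrometres.
#' @param classes Tissue classes to place (must include at least one; a
#'   degenerate single-class scene yields a warning downstream, not an
#'   error, to allow null experiments).
#' @param label_grid Optional explicit character label matrix overriding the
#'   random geometry.
#' @param amplitude Mean overall signal amplitude (counts x 1/cm).
#' @param amp_range Per-pixel multiplicative amplitude range (uniform).
#' @param snr Shot-noise signal-to-noise ratio at the spectrum peak
#'   (`Inf` = noise-free). Noise sd scales with sqrt(intensity).
#' @param background_level Fluorescence baseline scale relative to
#'   `amplitude` (0 = none).
#' @param cosmic_rate Cosmic-ray events per 1000 spectra.
#' @param cosmic_amp Spike amplitude range, as multiples of the local signal.
#' @param ambiguous_frac Probability that a region-boundary pixel is
#'   annotated `AMBIGUOUS` (emulates the histology-registration precision
#'   limit of one map pixel).
#' @param blob_smoothness Gaussian smoothing radius (pixels) of the random
#'   region geometry.
#' @param seed Optional per-scene RNG seed.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(nrow = 16, ncol = 16, step_size = 500,
                       classes = c("TUMOR", "CONNECTIVE", "GLAND",
                                   "MUSCLE", "NECROSIS"),
                       label_grid = NULL,
                       amplitude = 1000,
                       amp_range = c(0.6, 1.4),
                       snr = 25,
                       background_level = 0.5,
                       cosmic_rate = 2,
                       cosmic_amp = c(5, 50),
                       ambiguous_frac = 0.2,
                       blob_smoothness = 2.5,
                       seed = NULL) {
  stopifnot(nrow >= 1, ncol >= 1, cosmic_rate >= 0, background_level >= 0,
            snr > 0, all(classes %in% ANALYSIS_LABELS), length(classes) >= 1)
  if (!is.null(label_grid)) {
    label_grid <- as.matrix(label_grid)
    if (base::nrow(label_grid) != nrow || base::ncol(label_grid) != ncol)
      stop("label_grid shape must match nrow x ncol")
  }
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 step_size = step_size, classes = classes,
                 label_grid = label_grid, amplitude = amplitude,
                 amp_range = amp_range, snr = snr,
                 background_level = background_level,
                 cosmic_rate = cosmic_rate, cosmic_amp = cosmic_amp,
                 ambiguous_frac = ambiguous_frac,
                 blob_smoothness = blob_smoothness, seed = seed),
            class = "scene_spec")
}

#' Simulate one pixel spectrum
#'
#' Applies the generator forward model for a single pixel. With
#' `background = NULL` and `snr = Inf` the output is noise- and
#' background-free, and the band-ratio water estimator (R = 1) recovers
#' `water_fraction` to machine precision.
#'
#' @param profiles A [tissue_profiles()] object.
#' @param tissue A label from [ANALYSIS_LABELS] (or `"BACKGROUND"` for a
#'   no-tissue pixel carrying only residual moisture signal).
#' @param water_fraction Water mass fraction in \[0, 1\].
#' @param amplitude Overall amplitude A.
#' @param background Optional numeric baseline vector on the full axis.
#' @param snr Peak signal-to-noise ratio (`Inf` = none). Uses the current
#'   RNG stream; seed with `set.seed()` for reproducibility.
#' @return Finite non-negative intensity vector on the full axis.
#' @export
make_pixel_spectrum <- function(profiles, tissue, water_fraction,
                                amplitude = 1000, background = NULL,
                                snr = Inf) {
  stopifnot(inherits(profiles, "tissue_profiles"))
  if (water_fraction < 0 || water_fraction > 1)
    stop("water_fraction must lie in [0, 1]")
  if (identical(tissue, "BACKGROUND")) {
    mix <- 0.02 * profiles$water_band
  } else {
    if (!tissue %in% rownames(profiles$profiles))
      stop("unknown tissue label: ", tissue)
    mix <- (1 - water_fraction) * profiles$profiles[tissue, ] +
      water_fraction * profiles$water_band
  }
  s <- amplitude * mix
  if (!is.null(background)) s <- s + background
  if (is.finite(snr)) {
    peak <- max(s)
    if (peak > 0) {
      sd_i <- sqrt(pmax(s, 0) * peak) / snr
      s <- s + stats::rnorm(length(s), 0, sd_i)
    }
  }
  pmax(s, 0)
}

# smooth random fields -> argmax class labels (blob geometry)
random_label_grid <- function(nrow, ncol, classes, smoothness) {
  k <- length(classes)
  if (k == 1) return(matrix(classes, nrow, ncol))
  r <- ceiling(2 * smoothness)
  kern <- outer(stats::dnorm(-r:r, 0, smoothness),
                stats::dnorm(-r:r, 0, smoothness))
  kern <- kern / sum(kern)
  smooth_field <- function() {
    pad <- matrix(stats::rnorm((nrow + 2 * r) * (ncol + 2 * r)),
                  nrow + 2 * r, ncol + 2 * r)
    out <- matrix(0, nrow, ncol)
    for (i in seq_len(nrow)) for (j in seq_len(ncol))
      out[i, j] <- sum(pad[i:(i + 2 * r), j:(j + 2 * r)] * kern)
    out
  }
  fields <- lapply(seq_len(k), function(i) smooth_field())
  lab <- matrix("", nrow, ncol)
  for (i in seq_len(nrow)) for (j in seq_len(ncol))
    lab[i, j] <- classes[which.max(vapply(fields, function(f) f[i, j], 0))]
  lab
}

#' Generate one synthetic annotated spectral map
#'
#' Emulates a single mapping experiment: tissue regions laid out as random
#' blobs (or a supplied label grid), per-pixel water fractions drawn from
#' the tissue water distributions, smooth fluorescence backgrounds, shot
#' noise, cosmic-ray spikes, and an annotation mask whose region boundaries
#' may be marked `AMBIGUOUS`.
#'
#' @param scene A [scene_spec()].
#' @param profiles A [tissue_profiles()].
#' @param map_id,patient_id Identifiers stored in the map.
#' @return List with elements `map` (a [spectral_map()]), `mask`
#'   (an [annotation_mask()]) and `truth` (data frame of per-pixel `row`,
#'   `col`, `tissue`, `water`).
#' @export
generate_map <- function(scene = scene_spec(), profiles = tissue_profiles(),
                         map_id = "M01", patient_id = "P01") {
  stopifnot(inherits(scene, "scene_spec"), inherits(profiles, "tissue_profiles"))
  if (!is.null(scene$seed)) set.seed(scene$seed)
  nr <- scene$nrow; nc <- scene$ncol
  axis <- profiles$axis

  if (!is.null(scene$label_grid)) {
    labels <- scene$label_grid
  } else {
    labels <- random_label_grid(nr, nc, scene$classes, scene$blob_smoothness)
    if ("TUMOR" %in% scene$classes && !any(labels == "TUMOR")) {
      # guarantee a tumor focus: plant a small block at a random position
      br <- sample(seq_len(max(1, nr - 2)), 1)
      bc <- sample(seq_len(max(1, nc - 2)), 1)
      labels[br:min(nr, br + 2), bc:min(nc, bc + 2)] <- "TUMOR"
    }
  }
  if (length(unique(as.vector(labels))) < 2)
    warning("degenerate geometry: map contains a single class")

  wp <- profiles$water_params
  truth <- data.frame(row = rep(seq_len(nr), each = nc),
                      col = rep(seq_len(nc), times = nr),
                      tissue = as.vector(t(labels)),
                      water = NA_real_, stringsAsFactors = FALSE)
  for (t in unique(truth$tissue)) {
    sel <- truth$tissue == t
    if (t == "BACKGROUND") {
      truth$water[sel] <- 0.9
    } else {
      pr <- wp[wp$tissue == t, ]
      truth$water[sel] <- pmin(pmax(stats::rnorm(sum(sel), pr$mean, pr$sd),
                                    0.02), 0.97)
    }
  }

  # smooth per-map fluorescence baseline, degree-3 in scaled axis
  tt <- (axis - min(axis)) / diff(range(axis))
  dens_scale <- max(profiles$profiles)  # typical signal density
  bg_coef <- c(stats::runif(1, 0.5, 1.0), stats::runif(3, -0.3, 0.3))
  bg_base <- pmax(bg_coef[1] + bg_coef[2] * tt + bg_coef[3] * tt^2 +
                    bg_coef[4] * tt^3, 0) * dens_scale *
    scene$background_level * scene$amplitude

  n_px <- nr * nc
  spectra <- matrix(0, n_px, length(axis))
  for (i in seq_len(n_px)) {
    t_i <- truth$tissue[i]
    amp <- scene$amplitude *
      (if (t_i == "BACKGROUND") 0.5 else stats::runif(1, scene$amp_range[1],
                                                      scene$amp_range[2]))
    bg <- if (scene$background_level > 0)
      bg_base * stats::runif(1, 0.8, 1.2) else NULL
    spectra[i, ] <- make_pixel_spectrum(profiles, t_i, truth$water[i],
                                        amplitude = amp, background = bg,
                                        snr = scene$snr)
  }

  # cosmic rays: isolated 1-2 channel positive spikes
  n_events <- stats::rpois(1, scene$cosmic_rate * n_px / 1000)
  if (n_events > 0) {
    for (e in seq_len(n_events)) {
      px <- sample.int(n_px, 1)
      ch <- sample(seq(3, length(axis) - 3), 1)
      width <- sample(1:2, 1)
      local <- max(stats::median(spectra[px, ]), max(spectra[px, ch]), 1)
      amp <- stats::runif(1, scene$cosmic_amp[1], scene$cosmic_amp[2]) * local
      spectra[px, ch:(ch + width - 1)] <- spectra[px, ch:(ch + width - 1)] + amp
    }
  }

  # annotation: boundary pixels may be ambiguous (registration precision)
  mask <- labels
  if (scene$ambiguous_frac > 0 && length(unique(as.vector(labels))) > 1) {
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      nb <- c(if (i > 1) labels[i - 1, j], if (i < nr) labels[i + 1, j],
              if (j > 1) labels[i, j - 1], if (j < nc) labels[i, j + 1])
      if (any(nb != labels[i, j]) &&
          stats::runif(1) < scene$ambiguous_frac)
        mask[i, j] <- "AMBIGUOUS"
    }
  }

  map <- spectral_map(map_id, patient_id, axis, spectra, nr, nc,
                      scene$step_size)
  list(map = map, mask = annotation_mask(mask, map), truth = truth)
}

#' Generate a multi-map cohort with patient assignment
#'
#' Produces a model set and an independent test set of synthetic maps with
#' disjoint patient partitions. Patients are split between the sets
#' proportionally to map counts (`n_test_patients =
#' max(1, floor(patients * n_test / (n_model + n_test)))`), every patient
#' receives at least one map, and the per-map RNG streams are derived from
#' the master seed by fixed offsets so that cohorts are reproducible
#' map by map.
#'
#' @param n_model_maps,n_test_maps Number of maps in the model and test sets.
#' @param patients Total number of patients.
#' @param scene A [scene_spec()] template (per-map seeds are overridden).
#' @param profiles A [tissue_profiles()].
#' @param seed Master seed (integer).
#' @return List of class `raman_cohort`: entries with `map`, `mask`,
#'   `truth`, `role` (`"model"`/`"test"`); attributes `model_patients`,
#'   `test_patients`.
#' @export
generate_cohort <- function(n_model_maps, n_test_maps, patients,
                            scene = scene_spec(),
                            profiles = tissue_profiles(), seed = 1L) {
  stopifnot(n_model_maps >= 1, n_test_maps >= 1, patients >= 2)
  n_maps <- n_model_maps + n_test_maps
  n_test_pat <- max(1L, as.integer(floor(patients * n_test_maps / n_maps)))
  n_model_pat <- patients - n_test_pat
  if (n_model_pat < 1) stop("too few patients for a model set")
  if (n_model_maps < n_model_pat || n_test_maps < n_test_pat)
    stop("need at least one map per patient in each set")
  model_pat <- sprintf("P%02d", seq_len(n_model_pat))
  test_pat <- sprintf("P%02d", n_model_pat + seq_len(n_test_pat))
  if (length(intersect(model_pat, test_pat)))
    stop("overlapping patient assignment between model and test sets")

  set.seed(seed)
  assign_maps <- function(n, pats) {
    a <- c(pats, if (n > length(pats))
      sample(pats, n - length(pats), replace = TRUE))
    sample(a)  # shuffle so patient order carries no structure
  }
  pat_of <- c(assign_maps(n_model_maps, model_pat),
              assign_maps(n_test_maps, test_pat))
  roles <- c(rep("model", n_model_maps), rep("test", n_test_maps))

  cohort <- vector("list", n_maps)
  for (i in seq_len(n_maps)) {
    sc <- scene
    sc$seed <- as.integer((seed + 1009L * i) %% .Machine$integer.max)
    entry <- generate_map(sc, profiles, map_id = sprintf("M%02d", i),
                          patient_id = pat_of[i])
    entry$role <- roles[i]
    cohort[[i]] <- entry
  }
  structure(cohort, class = "raman_cohort",
            model_patients = model_pat, test_patients = test_pat,
            seed = seed)
}

#' @export
print.raman_cohort <- function(x, ...) {
  roles <- vapply(x, `[[`, "", "role")
  cat(sprintf("<raman_cohort> %d maps (%d model / %d test), %d + %d patients\n",
              length(x), sum(roles == "model"), sum(roles == "test"),
              length(attr(x, "model_patients")),
              length(attr(x, "test_patients"))))
  invisible(x)
}
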