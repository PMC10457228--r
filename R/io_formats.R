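# Data containers: wavenumber axis, spectral map, annotation mask, config.
# Grid convention (stated once, inherited everywhere): pixels are addressed
# (row, col), 1-based, row-major; spectra are stored as an n_pixel x n_channel
# matrix with pixel index (row - 1) * ncol + col.

#' Tissue label vocabulary
#'
#' The closed set of per-pixel annotation labels. `TUMOR` is the positive
#' class; the five non-cancerous tissue labels are pooled as the negative
#' class; `BACKGROUND` (no tissue) and `AMBIGUOUS` (unclear histology)
#' pixels never enter the analysis.
#'
#' @format Character vectors.
#' @export
TISSUE_LABELS <- c("TUMOR", "CONNECTIVE", "GLAND", "CARTILAGE", "MUSCLE",
                   "NECROSIS", "BACKGROUND", "AMBIGUOUS")

#' @rdname TISSUE_LABELS
#' @export
NONCANCER_LABELS <- c("CONNECTIVE", "GLAND", "CARTILAGE", "MUSCLE", "NECROSIS")

#' @rdname TISSUE_LABELS
#' @export
ANALYSIS_LABELS <- c("TUMOR", NONCANCER_LABELS)

#' Construct a wavenumber axis
#'
#' A validated, strictly increasing relative-wavenumber axis (1/cm). The
#' axis must resolve better than 5 1/cm and must cover both the
#' CH-stretching window (2800-3100 1/cm) and the OH band used for water
#' quantification (up to 3550 1/cm). Monotonicity is enforced here and
#' never re-checked downstream.
#'
#' @param values Numeric vector of relative wavenumbers in 1/cm.
#' @return A numeric vector of class `wavenumber_axis`.
#' @export
wavenumber_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 8 || anyNA(values) || any(!is.finite(values)))
    stop("axis must be a finite numeric vector with >= 8 points")
  d <- diff(values)
  if (any(d <= 0)) stop("axis must be strictly increasing")
  if (max(d) > 5) stop("axis spacing must be <= 5 1/cm")
  if (min(values) > 2800 || max(values) < 3550)
    stop("axis must cover the CH window [2800, 3100] and the OH window up to 3550 1/cm")
  structure(values, class = "wavenumber_axis")
}

#' Default wavenumber axis for synthetic maps
#'
#' 2500-4000 1/cm sampled every 2 1/cm (751 channels).
#' @return A `wavenumber_axis`.
#' @export
default_axis <- function() wavenumber_axis(seq(2500, 4000, by = 2))

#' Construct a spectral map
#'
#' A grid of spectra measured over a tissue-section surface on a shared
#' wavenumber axis. The map is the unit of grouped cross-validation.
#'
#' @param map_id,patient_id Character identifiers.
#' @param axis A [wavenumber_axis()].
#' @param spectra Numeric matrix, one row per pixel (row-major order),
#'   one column per axis channel. Intensities are arbitrary counts;
#'   negative values are permitted only after background subtraction.
#' @param nrow,ncol Grid dimensions.
#' @param step_size Grid step in micrometres, within \[250, 1000\].
#' @param pixel_valid Logical matrix (`nrow` x `ncol`); `FALSE` marks
#'   pixels with no tissue or excluded spectra.
#' @return An object of class `spectral_map`.
#' @export
spectral_map <- function(map_id, patient_id, axis, spectra, nrow, ncol,
                         step_size, pixel_valid = NULL) {
  axis <- if (inherits(axis, "wavenumber_axis")) axis else wavenumber_axis(axis)
  spectra <- as.matrix(spectra)
  if (!is.numeric(spectra) || any(!is.finite(spectra)))
    stop("spectra must be a finite numeric matrix")
  if (ncol(spectra) != length(axis))
    stop("every spectrum must have the same length as the axis (",
         ncol(spectra), " != ", length(axis), ")")
  if (base::nrow(spectra) != nrow * ncol)
    stop("spectra matrix must have nrow * ncol = ", nrow * ncol, " rows")
  if (step_size < 250 || step_size > 1000)
    stop("step_size must lie within [250, 1000] micrometres")
  if (is.null(pixel_valid)) pixel_valid <- matrix(TRUE, nrow, ncol)
  pixel_valid <- matrix(as.logical(pixel_valid), nrow, ncol)
  if (anyNA(pixel_valid)) stop("pixel_valid must be TRUE/FALSE")
  structure(
    list(map_id = as.character(map_id), patient_id = as.character(patient_id),
         axis = axis, spectra = spectra, nrow = as.integer(nrow),
         ncol = as.integer(ncol), step_size = as.numeric(step_size),
         pixel_valid = pixel_valid),
    class = "spectral_map")
}

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf("<spectral_map %s> patient %s: %d x %d pixels @ %g um, %d channels [%g, %g] 1/cm, %d valid\n",
              x$map_id, x$patient_id, x$nrow, x$ncol, x$step_size,
              length(x$axis), min(x$axis), max(x$axis), sum(x$pixel_valid)))
  invisible(x)
}

# row-major pixel index for (row, col)
pixel_index <- function(map, row, col) (row - 1L) * map$ncol + col

#' Construct an annotation mask
#'
#' Per-pixel tissue labels delineated on histology and projected onto the
#' Raman grid. The label vocabulary is closed ([TISSUE_LABELS]); unknown
#' strings are rejected, never coerced. Only non-`AMBIGUOUS`,
#' non-`BACKGROUND` pixels enter the analysis.
#'
#' @param labels Character matrix of labels, same grid shape as the map it
#'   annotates.
#' @param map Optional `spectral_map` to check the shape against.
#' @return A character matrix of class `annotation_mask`.
#' @export
annotation_mask <- function(labels, map = NULL) {
  labels <- as.matrix(labels)
  mode(labels) <- "character"
  bad <- setdiff(unique(as.vector(labels)), TISSUE_LABELS)
  if (length(bad))
    stop("annotation error: unknown label(s): ", paste(bad, collapse = ", "))
  if (!is.null(map) &&
      (base::nrow(labels) != map$nrow || base::ncol(labels) != map$ncol))
    stop("annotation error: mask shape ", base::nrow(labels), "x",
         base::ncol(labels), " does not match map grid ", map$nrow, "x", map$ncol)
  structure(labels, class = c("annotation_mask", "matrix"))
}

#' Analysis configuration
#'
#' Holds every tunable constant of the pipeline in one place. Defaults
#' follow the study protocol: quality gate at 5% of the overall mean
#' CH-region intensity, water outlier ceiling at 88%, Savitzky-Golay
#' order 3 / window 11, 3rd-order autofluorescence polynomial.
#'
#' @param oh_band,ch_band Integration limits (1/cm) of the OH and CH bands
#'   used for the water band ratio.
#' @param quality_band Range (1/cm) over which mean intensity is taken as
#'   the signal-quality measure.
#' @param water_cal_r Dimensionless calibration constant R of the band-ratio
#'   water estimator; 1 matches the synthetic generator, real instruments
#'   must supply a measured value.
#' @param quality_gate_fraction Pixels whose mean CH intensity falls below
#'   this fraction of the overall mean are excluded.
#' @param quality_gate_scope `"dataset"` (default) or `"map"`: whether the
#'   overall mean is taken across all maps of a run or per map.
#' @param quality_gate_stage `"post"` (default) or `"pre"`: whether the
#'   intensity measure is computed after or before background subtraction.
#' @param water_outlier_max Water fractions strictly above this are
#'   discarded as outliers.
#' @param sg_order,sg_window Savitzky-Golay polynomial order and window.
#' @param background_degree Degree of the autofluorescence baseline
#'   polynomial.
#' @param emsc_poly_order Baseline polynomial order inside the EMSC window.
#' @param ch_window CH-stretching analysis window (1/cm) for EMSC/PCA-LDA.
#' @param max_pc Largest candidate PC count for model selection.
#' @param cosmic_k,cosmic_window MAD multiplier and rolling-median window of
#'   the cosmic-ray detector.
#' @param seed Master RNG seed.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(oh_band = c(3350, 3550),
                            ch_band = c(2910, 2966),
                            quality_band = c(2700, 3100),
                            water_cal_r = 1.0,
                            quality_gate_fraction = 0.05,
                            quality_gate_scope = c("dataset", "map"),
                            quality_gate_stage = c("post", "pre"),
                            water_outlier_max = 0.88,
                            sg_order = 3L,
                            sg_window = 11L,
                            background_degree = 3L,
                            emsc_poly_order = 1L,
                            ch_window = c(2800, 3100),
                            max_pc = 20L,
                            cosmic_k = 8,
                            cosmic_window = 9L,
                            seed = 1L) {
  cfg <- list(oh_band = sort(as.numeric(oh_band)),
              ch_band = sort(as.numeric(ch_band)),
              quality_band = sort(as.numeric(quality_band)),
              water_cal_r = as.numeric(water_cal_r),
              quality_gate_fraction = as.numeric(quality_gate_fraction),
              quality_gate_scope = match.arg(quality_gate_scope),
              quality_gate_stage = match.arg(quality_gate_stage),
              water_outlier_max = as.numeric(water_outlier_max),
              sg_order = as.integer(sg_order),
              sg_window = as.integer(sg_window),
              background_degree = as.integer(background_degree),
              emsc_poly_order = as.integer(emsc_poly_order),
              ch_window = sort(as.numeric(ch_window)),
              max_pc = as.integer(max_pc),
              cosmic_k = as.numeric(cosmic_k),
              cosmic_window = as.integer(cosmic_window),
              seed = as.integer(seed))
  if (cfg$quality_gate_fraction < 0 || cfg$quality_gate_fraction >= 1)
    stop("quality_gate_fraction must lie in [0, 1)")
  if (cfg$sg_window %% 2L == 0L || cfg$sg_window <= cfg$sg_order)
    stop("sg_window must be odd and > sg_order")
  if (cfg$water_cal_r <= 0) stop("water_cal_r must be positive")
  structure(cfg, class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#'
#' The YAML file mirrors [analysis_config()] field for field; unknown
#' fields are rejected.
#'
#' @param path File path.
#' @param cfg An `analysis_config`.
#' @return `read_config` returns an `analysis_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write / read a spectral map container
#'
#' One self-describing container file per map holding the axis, the
#' spectrum grid, the annotation mask and the metadata atomically
#' (R serialization, version 3). `read_map(write_map(...))` reproduces all
#' fields bit-exactly. For interoperability a plain-text per-pixel TSV
#' export is available via [write_map_tsv()].
#'
#' @param map A `spectral_map`.
#' @param mask An `annotation_mask` with the same grid shape.
#' @param path File path.
#' @return `write_map` returns `path` invisibly; `read_map` returns
#'   `list(map, mask)` after re-validating both.
#' @export
write_map <- function(map, mask, path) {
  stopifnot(inherits(map, "spectral_map"))
  mask <- annotation_mask(mask, map)
  saveRDS(list(format = "ramanmap/1", map = unclass(map),
               mask = unclass(mask)), path, version = 3)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "ramanmap/1") ||
      is.null(obj$map$axis) || is.null(obj$map$spectra))
    stop("format error: not a ramanmap container (missing axis/grid)")
  m <- obj$map
  map <- spectral_map(m$map_id, m$patient_id, m$axis, m$spectra,
                      m$nrow, m$ncol, m$step_size, m$pixel_valid)
  mask <- annotation_mask(obj$mask, map)
  list(map = map, mask = mask)
}

#' Export a map as a per-pixel TSV table
#'
#' Columns: `row`, `col` (1-based), `label`, `valid`, and optionally
#' `water` and `score` when a water map and/or LDA scores are supplied.
#'
#' @param map A `spectral_map`.
#' @param mask An `annotation_mask`.
#' @param path Output path.
#' @param water Optional `water_map` for the same grid.
#' @param scores Optional numeric matrix of classifier scores (grid shape).
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(map, mask, path, water = NULL, scores = NULL) {
  mask <- annotation_mask(mask, map)
  idx <- expand.grid(col = seq_len(map$ncol), row = seq_len(map$nrow))
  df <- data.frame(row = idx$row, col = idx$col,
                   label = mapply(function(r, c) mask[r, c], idx$row, idx$col),
                   valid = mapply(function(r, c) map$pixel_valid[r, c],
                                  idx$row, idx$col))
  if (!is.null(water))
    df$water <- mapply(function(r, c) water$w[r, c], idx$row, idx$col)
  if (!is.null(scores))
    df$score <- mapply(function(r, c) scores[r, c], idx$row, idx$col)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# trapezoidal band area over axis points lying inside [limits[1], limits[2]]
band_area <- function(axis, y, limits) {
  idx <- which(axis >= limits[1] & axis <= limits[2])
  if (length(idx) < 2) stop("band [", limits[1], ", ", limits[2],
                            "] contains fewer than 2 axis points")
  x <- axis[idx]; yy <- y[idx]
  sum(diff(x) * (yy[-length(yy)] + yy[-1]) / 2)
}

# matrix version: rows are spectra
band_area_matrix <- function(axis, Y, limits) {
  idx <- which(axis >= limits[1] & axis <= limits[2])
  x <- axis[idx]
  w <- numeric(length(idx))
  dx <- diff(x)
  w[-length(w)] <- w[-length(w)] + dx / 2
  w[-1] <- w[-1] + dx / 2
  as.vector(Y[, idx, drop = FALSE] %*% w)
}
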