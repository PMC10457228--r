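# End-to-end study pipeline: generate -> preprocess -> water arm ->
# CH-stretching PCA-LDA arm -> evaluation.

# row-major label vector of a mask
mask_vector <- function(mask) as.vector(t(unclass(mask)))

# analysis pixels of one preprocessed map entry: valid + unambiguous tissue
analysis_selection <- function(entry) {
  v <- as.vector(t(entry$map$pixel_valid))
  lab <- mask_vector(entry$mask)
  v & lab %in% ANALYSIS_LABELS
}

#' Run the full two-arm study on a synthetic cohort
#'
#' Reproduces the complete experimental design on synthetic data:
#' a cohort of `n_model_maps` model maps and `n_test_maps` independent test
#' maps with disjoint patient sets is generated, preprocessed (cosmic-ray
#' removal, background subtraction, quality gate), and analysed along two
#' arms. The water arm estimates a per-pixel water fraction on every map,
#' applies the outlier rule and the 3x3 smoothing, pools annotated pixels
#' over all maps and compares tumor vs non-cancerous water with a Wilcoxon
#' rank-sum test and ROC AUC. The CH arm restricts spectra to the
#' CH-stretching window, applies EMSC (water interferent) and
#' Savitzky-Golay filtering, selects the PC count by leave-one-map-out
#' validation on the model set, fits the final PCA-LDA model and validates
#' it on the independent test set, reporting the ROC, the Youden
#' sensitivity/specificity and the per-tissue false-positive breakdown.
#'
#' The run is a pure function of (configuration, seed): the same inputs
#' reproduce the same results object.
#'
#' @param cfg An [analysis_config()]; its `seed` is used unless `seed` is
#'   given.
#' @param scene A [scene_spec()] template for every map.
#' @param profiles A [tissue_profiles()].
#' @param n_model_maps,n_test_maps,patients Cohort shape (defaults: 25
#'   model maps and 9 test maps from 22 patients, split 17/5).
#' @param seed Master seed overriding `cfg$seed`.
#' @return An object of class `raman_study`; see Details for the fields.
#' @details The result contains `manifest` (config snapshot, seed, cohort
#'   shape, per-stage counts), `water` (pooled comparison + per-map water
#'   maps), `selection` (AUC-vs-p table and chosen p), `model` (the final
#'   `pcalda_model`), `validation` (pooled test scores, ROC, Youden point,
#'   `fp_breakdown`) and `model_roc` (pooled leave-one-map-out ROC at the
#'   chosen p).
#' @export
run_full_study <- function(cfg = analysis_config(),
                           scene = scene_spec(),
                           profiles = tissue_profiles(),
                           n_model_maps = 25, n_test_maps = 9, patients = 22,
                           seed = NULL) {
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  cohort <- generate_cohort(n_model_maps, n_test_maps, patients,
                            scene = scene, profiles = profiles, seed = seed)
  pre <- preprocess_cohort(cohort, cfg)
  report <- attr(pre, "report")
  roles <- vapply(pre, `[[`, "", "role")

  ## ---- water arm (all maps, as in the mapping protocol) ----
  water_maps <- list()
  groups <- list()
  n_outliers <- 0L
  for (entry in pre) {
    wm <- compute_water_map(entry$map, cfg)
    wm <- apply_outlier_rule(wm, cfg)
    n_outliers <- n_outliers + wm$n_discarded_outlier
    wm <- smooth_map(wm)
    water_maps[[entry$map$map_id]] <- wm
    g <- tryCatch(collect_groups(wm, entry$mask), error = function(e) NULL)
    if (!is.null(g)) groups[[length(groups) + 1L]] <- g
  }
  pooled <- pool_groups(groups)
  water_res <- compare_water(pooled)

  ## ---- CH-stretching arm ----
  win <- cfg$ch_window
  entries_ch <- lapply(pre, function(entry) {
    sel <- analysis_selection(entry)
    rw <- restrict_window(entry$map$spectra[sel, , drop = FALSE],
                          entry$map$axis, win)
    list(spectra = rw$spectra, axis = rw$axis,
         labels = mask_vector(entry$mask)[sel],
         map_id = entry$map$map_id, patient_id = entry$map$patient_id,
         role = entry$role)
  })
  model_idx <- which(roles == "model")
  test_idx <- which(roles == "test")
  model_pool <- do.call(rbind, lapply(entries_ch[model_idx], `[[`, "spectra"))
  interf <- water_interferent(profiles, win)
  emsc <- emsc_model(model_pool, entries_ch[[1]]$axis,
                     interferents = interf$spectrum,
                     poly_order = cfg$emsc_poly_order)
  n_degenerate <- 0L
  for (i in seq_along(entries_ch)) {
    res <- emsc_correct_matrix(entries_ch[[i]]$spectra, emsc)
    keep <- res$valid
    n_degenerate <- n_degenerate + sum(!keep)
    entries_ch[[i]]$spectra <- sg_filter(res$corrected[keep, , drop = FALSE],
                                         cfg$sg_order, cfg$sg_window)
    entries_ch[[i]]$labels <- entries_ch[[i]]$labels[keep]
  }

  model_maps <- lapply(entries_ch[model_idx], function(e)
    list(spectra = e$spectra, labels = e$labels == "TUMOR",
         map_id = e$map_id))
  selection <- select_pc_count(model_maps, max_p = cfg$max_pc)
  p_star <- selection$chosen_p
  model_roc <- roc_curve(selection$pooled$scores[[p_star]],
                         selection$pooled$labels[[p_star]])

  final <- fit_pcalda(
    do.call(rbind, lapply(entries_ch[model_idx], `[[`, "spectra")),
    unlist(lapply(entries_ch[model_idx], function(e) e$labels == "TUMOR")),
    p = p_star,
    map_ids = vapply(entries_ch[model_idx], `[[`, "", "map_id"),
    patient_ids = vapply(entries_ch[model_idx], `[[`, "", "patient_id"))

  test_maps <- lapply(entries_ch[test_idx], function(e)
    list(spectra = e$spectra, labels = e$labels == "TUMOR",
         map_id = e$map_id, patient_id = e$patient_id))
  val <- validate_model(final, test_maps)
  val_roc <- roc_curve(val$scores, val$labels)
  val_youden <- youden_point(val_roc)
  test_tissue <- unlist(lapply(entries_ch[test_idx], `[[`, "labels"))
  fp <- fp_breakdown(val$scores, test_tissue, val_youden$threshold)

  manifest <- list(
    seed = seed, config = unclass(cfg),
    cohort = list(n_model_maps = n_model_maps, n_test_maps = n_test_maps,
                  patients = patients,
                  model_patients = attr(cohort, "model_patients"),
                  test_patients = attr(cohort, "test_patients")),
    counts = list(
      n_pixels = sum(report$n_total),
      n_excluded_quality = sum(report$n_excluded_quality),
      n_water_outliers = n_outliers,
      n_degenerate_emsc = n_degenerate,
      n_analysis_model = sum(vapply(model_maps, function(e)
        length(e$labels), 0L)),
      n_analysis_test = length(val$labels)),
    quality_report = report)

  structure(list(manifest = manifest, water = c(water_res,
                                                list(maps = water_maps)),
                 selection = selection, model = final,
                 model_roc = model_roc,
                 validation = list(scores = val$scores, labels = val$labels,
                                   roc = val_roc, youden = val_youden,
                                   fp_breakdown = fp, auc = val_roc$auc)),
            class = "raman_study")
}

#' @export
print.raman_study <- function(x, ...) {
  m <- x$manifest
  cat("== high-wavenumber Raman map study (synthetic cohort) ==\n")
  cat(sprintf("cohort: %d model + %d test maps, %d/%d patients, seed %d\n",
              m$cohort$n_model_maps, m$cohort$n_test_maps,
              length(m$cohort$model_patients), length(m$cohort$test_patients),
              m$seed))
  cat(sprintf("pixels: %d total, %d excluded by quality gate, %d water outliers\n",
              m$counts$n_pixels, m$counts$n_excluded_quality,
              m$counts$n_water_outliers))
  cat(sprintf("water arm:  AUC = %.3f, Wilcoxon p = %.3g (tumor %0.1f%% vs non-cancerous %0.1f%% water)\n",
              x$water$auc, x$water$p_value, 100 * x$water$mean_tumor,
              100 * x$water$mean_noncancer))
  cat(sprintf("CH arm:     chosen p = %d, leave-one-map-out AUC = %.3f\n",
              x$selection$chosen_p, x$model_roc$auc))
  cat(sprintf("validation: AUC = %.3f, Youden sensitivity = %.2f / specificity = %.2f\n",
              x$validation$auc, x$validation$youden$sensitivity,
              x$validation$youden$specificity))
  if (nrow(x$validation$fp_breakdown)) {
    cat("false-positive fraction by tissue:\n")
    fb <- x$validation$fp_breakdown
    for (i in seq_len(nrow(fb)))
      cat(sprintf("  %-10s %3.0f%%  (%d/%d)\n", fb$tissue[i],
                  100 * fb$fraction[i], fb$n_fp[i], fb$n[i]))
  }
  invisible(x)
}
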