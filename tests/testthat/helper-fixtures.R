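# Shared fixtures, built in code. A coarser 5 1/cm axis keeps most tests
# fast; the default 2 1/cm axis is used where resolution matters.

coarse_axis <- function() wavenumber_axis(seq(2550, 4000, by = 5))

coarse_profiles <- function(delta = 0.05)
  tissue_profiles(axis = coarse_axis(), delta = delta)

# deterministic two-class checkerboard-ish label grid
two_class_grid <- function(nr, nc, classes = c("TUMOR", "MUSCLE")) {
  g <- matrix(classes[2], nr, nc)
  g[seq_len(ceiling(nr / 2)), ] <- classes[1]
  g
}

# small noise-free-ish map for container tests
make_test_entry <- function(seed = 7, nr = 6, nc = 5, snr = 50,
                            profiles = coarse_profiles()) {
  sc <- scene_spec(nrow = nr, ncol = nc, snr = snr, cosmic_rate = 0,
                   background_level = 0.2, ambiguous_frac = 0,
                   label_grid = two_class_grid(nr, nc), seed = seed)
  generate_map(sc, profiles, map_id = paste0("T", seed), patient_id = "PX")
}

# independent rank-based Mann-Whitney AUC (oracle)
mw_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels); n2 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# cheap two-class CH separation measure used by generator property tests:
# EMSC + SG + PCA-LDA trained on half the spectra, AUC on the other half
split_half_auc <- function(spectra, labels, axis, p = 5) {
  rw <- restrict_window(spectra, axis)
  labels <- as.logical(labels)
  idx_tr <- c(which(labels)[c(TRUE, FALSE)], which(!labels)[c(TRUE, FALSE)])
  em <- emsc_model(rw$spectra[idx_tr, ], rw$axis)
  co <- emsc_correct_matrix(rw$spectra, em)$corrected
  co <- sg_filter(co)
  fit <- fit_pcalda(co[idx_tr, , drop = FALSE], labels[idx_tr], p = p)
  s <- score_spectra(fit, co[-idx_tr, , drop = FALSE])
  roc_curve(s, labels[-idx_tr])$auc
}
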