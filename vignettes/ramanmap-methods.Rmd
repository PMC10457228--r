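---
title: "Methods: high-wavenumber Raman map analysis in ramanmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-wavenumber Raman map analysis in ramanmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanmap)
```

## Scope and data model

`ramanmap` analyses grids of high-wavenumber (HWVN, 2500–4000 cm⁻¹) Raman
spectra measured over excised tissue sections, with the goal of
discriminating squamous cell carcinoma from the surrounding non-cancerous
tissue structures. The unit of data is the **map** (`spectral_map`): a
rectangular pixel grid (step 250–1000 µm) with one intensity vector per
pixel on a shared, strictly increasing wavenumber axis (spacing ≤ 5 cm⁻¹,
covering at least the CH window 2800–3100 cm⁻¹ and the OH quantification
band up to 3550 cm⁻¹). An `annotation_mask` carries per-pixel histology
labels from a closed vocabulary (`TUMOR`, `CONNECTIVE`, `GLAND`,
`CARTILAGE`, `MUSCLE`, `NECROSIS`, `BACKGROUND`, `AMBIGUOUS`); only
unambiguous tissue pixels enter any statistic. The map — not the pixel —
is the grouping unit of all cross-validation, because spectra within one
map share a patient, an acquisition session, and an instrument state.

Axis monotonicity and mask/grid agreement are enforced at construction and
never re-checked downstream. Grid coordinates are 1-based `(row, col)`,
row-major; spectra are stored as an `n_pixel × n_channel` matrix in that
pixel order. Maps round-trip bit-exactly through `write_map()`/`read_map()`
(one atomic self-describing serialized file per map); a plain-text TSV
export (`write_map_tsv()`) provides interoperability. All tunable
constants live in `analysis_config()`, which mirrors a YAML file
field-for-field.

## Preprocessing

Instrument wavenumber calibration and detector-efficiency correction are
out of scope: the package assumes spectra already on a calibrated relative
wavenumber axis.

**Cosmic rays** are isolated 1–2-channel positive spikes. The detector
compares each channel against a rolling median (window 9); channels whose
residual exceeds 8 robust standard deviations (MAD) are candidates, and
only candidate runs of at most 2 channels are treated as spikes — wider
above-threshold features are real bands and are left untouched. Spikes are
replaced by linear interpolation of the flanking channels (one-sided at
the spectrum boundary). The operation is idempotent and leaves every
non-spike channel bit-identical.

**Autofluorescence background** is modelled as a 3rd-order polynomial on
the full HWVN range. A single unconstrained least-squares fit would cut
through the Raman peaks, so the fit is iterated with peak clipping: after
each of up to 20 iterations, data above the fitted curve are clamped to
it, and the fit converges (tolerance 1e-8 on coefficient change, relative
to the spectrum scale) to a curve hugging the baseline under the bands.
The signal-free stretches at both ends of the HWVN range (below
~2800 cm⁻¹ and above ~3750 cm⁻¹) anchor the polynomial; a small residual
bias under the very broad OH band remains and is visible in the water
estimates (a few percent at most on synthetic data — see the generator
tests), which is acceptable because the water analysis is interpreted
through ranks (Wilcoxon, AUC), not absolute calibration.

**Quality gate.** The mean intensity over 2700–3100 cm⁻¹ is the per-pixel
signal-quality measure; pixels below 5% (`quality_gate_fraction`) of the
overall mean are flagged invalid. Two choices here were genuinely open:

* *Scope of "overall mean":* per dataset (all maps of a run, the default)
  or per map (`quality_gate_scope`). A dataset-wide scope drops entire
  low-quality experiments, matching a workflow in which whole experiments
  can be excluded for insufficient quality.
* *Stage:* the gate is computed after background subtraction by default
  (`quality_gate_stage = "post"`), so the measure reflects Raman rather
  than fluorescence intensity; the pre-subtraction variant is available
  since the protocol wording does not fix the order.

## Water-concentration arm

Tissue water fraction is estimated per pixel from the band-area ratio
ρ = A(OH) / A(CH) (trapezoidal integration; OH 3350–3550 cm⁻¹, CH
2910–2966 cm⁻¹ by default) mapped through

w = ρ / (ρ + R),

with R a dimensionless instrument calibration constant. The mapping is
monotone in ρ, symmetric at w = 0.5 when ρ = R, and clipped to [0, 1]; a
non-positive CH band area invalidates the pixel. The ratio-to-fraction
form was chosen over a linear calibration because it is bounded and exact
under the two-component (water + organic matrix) mixing model the
generator implements; R defaults to 1, the value for which the synthetic
generator is exactly inverted, and **must** be supplied from a calibration
measurement for real instruments. Water fractions strictly above 0.88 are
physically implausible in tissue and are discarded as outliers (exactly
0.88 is retained). For display, maps are smoothed with a 3×3 average
filter over valid neighbours only; invalid pixels are never imputed and
render black. Group statistics always use the raw (unsmoothed) estimates.

Tumor vs pooled non-cancerous water is compared with a two-sided Wilcoxon
rank-sum test — exact enumeration when both groups have ≤ 10 tie-free
values, otherwise the normal approximation with tie-corrected variance —
and with the ROC AUC using the water fraction as score. The AUC is
computed by the package's tie-grouped trapezoidal ROC, which equals the
Mann-Whitney U/(n₁n₂) formulation; the equality is asserted in tests.

## CH-stretching arm

The CH window 2800–3100 cm⁻¹ carries protein/lipid compositional
information that is complementary to, and must be made independent of, the
water signal. The model chain is **EMSC → Savitzky-Golay → PCA → LDA**,
in that fixed order (smoothing after EMSC reduces noise going into the
PCA; smoothing before EMSC would equivalently alter all design columns).

**EMSC.** Each window spectrum is regressed on a design of: baseline
polynomial (order 1 inside the window, configurable 0–2 — the global
3rd-order background is already gone), the reference spectrum m (mean of
the model-set analysis spectra), and interferent spectra (a pure-water
spectrum restricted to the window; the generator supplies its own via
`water_interferent()`, real data needs a measured one). The corrected
spectrum is `(s − baseline − interferent parts) / b`, where `b` is the
reference coefficient. Two invariances follow from the linear algebra and
are enforced by test: scaling `s` by any κ > 0 and adding any multiple of
the water interferent leave the output unchanged (to < 1e-8 RMS). Spectra
with |b| < 1e-8 carry no reference-like signal and are flagged invalid.
Interferent columns are normalized to unit length for conditioning; a
rank-deficient design is rejected at model construction.

**Savitzky-Golay.** Order 3, window 11 — the standard compromise
preserving band shape (any cubic is reproduced exactly) while averaging
11-channel noise. Edges use the polynomial fit on the available one-sided
window. The vectorized matrix path is verified channel-for-channel against
the reference implementation and against the published 1/429 convolution
weights.

**PCA-LDA.** PCA is mean-centred and unscaled (channels share units;
autoscaling would inflate noise channels). For the classifier, PCA is
fitted on the pooled model-set spectra; per-map PCA is used only for the
RGB score images (`pca_rgb_map()`, PCs 1–3 min-max scaled per channel).
The Fisher discriminant on the first p score dimensions is
w ∝ S_w⁻¹(μ_tumor − μ_non); a singular within-class scatter receives a
ridge of 1e-8·trace(S_w)/p. Scores are oriented so tumor is positive, and
the training-ROC Youden threshold is stored with the model.

**Model selection.** p is chosen by leave-one-map-out validation: for each
candidate p (1…`max_pc`, default 20) and each held-out map, the model is
refitted on the remaining maps and the held-out pixels are scored; all
held-out scores are pooled into one ROC per p, and the smallest p
attaining the maximum AUC wins (parsimony at ties). Folds whose training
half loses a class are skipped with a warning. The final model is refitted
at the chosen p on the full model set and validated — without refitting —
on test maps whose patients are verified disjoint from the training
patients.

## Evaluation

The ROC is evaluated at every unique score (ties grouped into one step)
with endpoints (0,0) and (1,1); AUC is the trapezoidal integral. The
classification rule is `score ≥ threshold → tumor`, stated once and used
everywhere. The Youden point maximizes sensitivity + specificity − 1, with
ties broken towards higher specificity, then lower threshold. The
false-positive breakdown reports, per non-cancerous tissue type, the
fraction of its spectra at or above the threshold; types without spectra
are reported as absent rather than zero.

## The synthetic generator

Real clinical map data are not publicly deposited, so the generator is a
first-class module that defines the study conditions for all end-to-end
tests. Its forward model per pixel is

spectrum = A·[(1 − w)·P_tissue + w·W] + background + shot noise,

with P a per-tissue CH profile (Gaussian mixture around the
2850/2885/2930/2960/3010 cm⁻¹ CH stretches, zero outside 2800–3100 cm⁻¹),
W a broad OH band (Gaussian, centre 3400 cm⁻¹, FWHM 260 cm⁻¹ — only the
band-ratio behaviour matters downstream, so a single Gaussian suffices),
and A a per-pixel amplitude (uniform 0.6–1.4 of the scene amplitude; this
is the multiplicative variation EMSC must remove). Key calibration
choices:

* P and W are normalized so their quantification-band areas are equal
  (shared fraction β = 0.35 of unit total area), and W is smoothly tapered
  to exactly zero below 3080 cm⁻¹, i.e. outside the CH quantification
  band. Then ρ = w/(1 − w) identically, and the estimator with R = 1
  recovers w to machine precision on noise-free pixels — the ground-truth
  oracle the test suite relies on. The taper still leaves genuine water
  signal inside the 2800–3100 cm⁻¹ analysis window, so the EMSC water
  interferent is doing real work.
* The CH effect size δ scales every tissue's deviation (unit-L2,
  area-neutral Gaussian-difference directions) from a shared base profile,
  so δ is an L2 distance scale between unit-area profiles and δ = 0
  collapses all tissues onto one profile — the clean null case. Relative
  magnitudes order the types so necrosis and gland are most tumor-like and
  muscle least, mirroring which tissues confuse the classifier. The
  default δ = 0.05 was calibrated once to give moderate separation
  (held-out AUC near 0.9 under default noise) and is not otherwise
  meaningful.
* Water-fraction distributions are highly overlapping by design: means
  0.72–0.765 with sd 0.045 across types, all near the ~75% water typical
  of these tissues, so the water arm lands at low discriminative power
  (AUC ≈ 0.55–0.6) while remaining statistically significant at large n.
* Shot noise has sd ∝ √intensity, scaled so the peak signal-to-noise
  ratio is `snr` (default 25, a realistic value for ~1 s acquisitions).
  Spectra are clamped at zero, so generated intensities are non-negative.
  Cosmic rays arrive at 2 events / 1000 spectra (amplitude 5–50× the
  local signal, 1–2 channels). Fluorescence backgrounds are random
  degree-3 polynomials at half the signal scale.
* Tissue geometry: per-class smoothed-noise fields thresholded by argmax
  give contiguous blobs; an explicit label grid can be supplied for
  deterministic tests. Region-boundary pixels are annotated `AMBIGUOUS`
  with probability 0.2, emulating the one-pixel registration precision of
  histology-to-map projection. A single-class map warns but is allowed
  (null experiments need it).
* Cohorts use one master seed; per-map streams are derived by fixed
  offsets, so any map regenerates identically. Patients are split between
  model and test sets proportionally to map counts (25/9 maps from 22
  patients gives the 17/5 split), each patient receives at least one map,
  and the partitions are disjoint by construction.

What the generator does **not** emulate: physically calibrated Raman
cross-sections, wavenumber miscalibration, detector nonlinearity,
spatially correlated noise, intra-tumor heterogeneity beyond the water
distribution, and depth effects. Passing tests therefore demonstrate
correctness of the algorithms under the stated statistical structure, not
clinical performance on real tissue.

## Problem sizes and determinism

The default study shape is 25 model + 9 test maps of 16×16 pixels
(8 704 spectra), which keeps a full two-arm run under a minute on one
core; the test suite uses smaller grids (and a 5 cm⁻¹ axis) for unit
tests and the full shape for end-to-end checks. Every stochastic step
draws from R's RNG seeded explicitly, so `run_full_study(seed = s)` is a
pure function of its configuration and seed.

## Known limitations

* The band-ratio calibration constant R and the EMSC water interferent
  must come from instrument measurements for real data; the defaults are
  generator-consistent only.
* The iterative polynomial baseline slightly underestimates intensity
  under the broad OH band (rank statistics absorb this; absolute water
  percentages carry a bias of up to a few percent).
* Leave-one-map-out pooling concatenates fold scores whose LDA scales may
  differ slightly; this is the standard pooled-ROC convention and is what
  the brute-force oracle verifies.
* No confidence intervals on AUC are reported.
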