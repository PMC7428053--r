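---
title: "Methods: spectral model, classification pipeline, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral model, classification pipeline, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanidc)
```

## The problem

Intraductal carcinoma of the prostate (IDC-P) marks aggressive disease but
has no clinically established molecular biomarker; it is diagnosed on
morphology alone and is easily confused with high-grade prostatic
intraepithelial neoplasia (HGPIN), a lesion with the opposite clinical
implication. Confocal Raman micro-spectroscopy measures a molecular
fingerprint of a few cells — vibrational bands of proteins, lipids, DNA and
RNA across the 602–1,726 cm⁻¹ fingerprint region — directly on routine
formalin-fixed tissue mounted on aluminum slides. This package implements a
complete diagnostic pipeline over such spectra: background removal,
sparse feature selection, kernel-SVM classification with patient-grouped
cross-validation, frozen-model testing on independent cohorts, and
molecular interpretation of the selected wavenumbers.

## The classification pipeline and its assumptions

**Background removal.** Raw spectra are dominated by tissue
autofluorescence and the aluminum substrate, both smooth on the scale of a
Raman line. The rolling-ball baseline is the 1-D morphological opening
(running minimum then running maximum with a half-width-`radius_points`
window) followed by a boxcar smoothing pass of the same window, capped at
the raw signal so the baseline never exceeds it. Corrected intensity is
the raw signal minus baseline, clipped at zero because Raman intensities
are physically non-negative. The method assumes nuisance structure is
*broader* than the radius and signal structure *narrower*: with the
default `radius_points = 50` (~55 cm⁻¹ at 1.1 cm⁻¹ spacing) a 12 cm⁻¹-FWHM
tissue line loses under ~10% of its height while smooth backgrounds reduce
to under 5% residual. The radius is not fixed by the acquisition protocol the package follows;
50 is this package's default, it is exposed everywhere, and
`radius_sensitivity()` tabulates how cross-validated metrics move with it
rather than pretending the value is known.

**Standardization.** Each wavenumber is centered and scaled to unit
variance. The statistics are fitted on the *training* cohort only and
reused frozen on every testing cohort. The alternative — refitting on each
cohort — would leak distributional information from the test set into the
decision; since the study design is explicitly about external validation,
the leak-free convention is the only defensible one, and it is enforced by
the API (`fit_standardization()` / `apply_standardization()` are separate
steps). Features constant in training map to zero with a warning.

**Feature selection.** A linear SVM with squared-hinge loss and an L1
penalty, `min ‖w‖₁ + C Σ max(0, 1 − yᵢ(xᵢᵀw+b))²`, zeroes out most of the
>1,000 wavenumbers; the survivors are the discriminative features. No
installed R package offers this exact estimator, so the package solves it
directly with FISTA proximal-gradient descent: soft-thresholding yields
exact zeros, the step size comes from a power-iteration bound on the
Lipschitz constant, initialization is the zero vector, and a monotone
restart guards the acceleration — the solver is fully deterministic. Tests
cross-check its selections against lasso-penalized logistic regression
(glmnet), which shares the sparsity mechanism but not the loss.

**Classification.** A Gaussian-kernel SVM (libsvm via e1071) on the
selected features. Decision scores are oriented so that larger means more
likely positive class, and a test verifies they equal the explicit kernel
expansion Σ αᵢyᵢK(xᵢ, x) + b from the stored dual coefficients.

**Model selection.** Grid search over `fs_C ∈ {0.05, 0.1, 0.2, 0.35,
0.5}`, `svm_C ∈ {0.1, 1, 10, 100, 1000}`, `γ ∈ {10⁻⁴, 10⁻³, 10⁻², 10⁻¹}` —
log-spaced grids spanning the study's stated ranges, which name bounds but
not individual grid points. Performance per combination is the mean accuracy over
5 patient-grouped, class-stratified folds. Two genuinely open choices were
resolved as follows:

* *Nesting.* Whether standardization and feature selection should be
  refitted inside each fold is a genuine design choice. Both modes are
  implemented (`nested` argument of `grid_search_train()`); the default is
  nested, because fitting them once on the full training set before
  cross-validation lets every fold's validation rows influence the
  features it is judged on and inflates fold estimates.
* *Tie-breaking.* Mean fold accuracy does not define an order among
  tied combinations; ties prefer smaller `svm_C`, then smaller `γ`, then
  smaller `fs_C` — consistently toward simpler, less flexible models.

The winning combination is refitted on the complete training cohort and
frozen. Class imbalance (a handful of IDC-P cores against hundreds of
cancer cores) is left to the SVM cost parameter, as no reweighting is
reported for the original models.

**Aggregation.** Spectrum-level contrasts (lymphocyte vs. cancer, benign
vs. cancer) classify individual acquisitions. The IDC-P contrasts pool
`idcp` and `idcp_adj_cancer` spectra — intraductal carcinoma and the
invasive cancer adjacent to it on the same core are molecularly similar
enough that separating them fails — and average all spectra of a core into
one observation. For HGPIN vs. IDC-P the aggregation of the HGPIN side is
left open by the protocol; the default keeps HGPIN at spectrum
level (`hgpin_unit = "core_mean"` switches it), since HGPIN cores carry no
paired lesion to pool.

**Operating point and reporting.** ROC curves sweep every distinct score
(ties enter and leave the positive set together); AUC is the trapezoidal
area, equivalent to the tie-corrected Mann–Whitney statistic; the decision
threshold is the point with minimal Euclidean distance to (0, 1) in
(1 − specificity, sensitivity) space. Accuracy, sensitivity and
specificity are reported in percent at both available row units (spectrum
or core, depending on the contrast). Peak assignment matches each selected
wavenumber to the nearest reference band center within a tolerance:
default 8 cm⁻¹, with 15 cm⁻¹ exposed because some reference
feature-to-band offsets (e.g. a 1,470 cm⁻¹ feature on the 1,484 cm⁻¹
band) exceed 8.

## The synthetic cohort generator

The generator exists so that every pipeline stage is exercised, and its
statistical assumptions checked, without the original spectra. It emulates:

* **Axis**: 602–1,726 cm⁻¹ at 1.1 cm⁻¹ spacing (1,022 features).
* **Cohort structure**: per-class patient counts, 1–6 cores per patient,
  4 acquisitions per core, following the compositions of the
  three emulated study arms (benign 99/49/68 patients, invasive cancer 272/76/135,
  IDC-P 15/14/9, HGPIN 64/9/13 for training and the two testing cohorts).
  Lymphocyte compositions per cohort are not part of the
  emulated protocol; 40/15/20 is this package's choice, large enough to train
  the lymphocyte contrast. Each IDC-P patient's intraductal cores carry
  half their acquisitions as `idcp` and half as `idcp_adj_cancer`,
  emulating cores annotated with both regions.
* **Baselines**: a smooth decreasing degree-4 fluorescence polynomial of
  amplitude ~400 plus one broad Gaussian
  (center 900 cm⁻¹, FWHM 600 cm⁻¹, amplitude ~150) for the aluminum
  substrate.
* **Signal**: a shared set of 25 tissue Raman lines (Gaussian, FWHM
  12 cm⁻¹, a typical tissue linewidth; line shapes are a package choice),
  phenylalanine 1,003 cm⁻¹ strongest.
* **Class structure**: at every feature wavenumber of the packaged
  reference tables, the class reported as increased receives a positive
  Gaussian component and the opposite class of that contrast the mirrored
  negative one, of amplitude `effect_size × effect_ref_amplitude`
  (default 0.25 × 40). The reference tables record *directions* only,
  never effect sizes, so `effect_size` is a free parameter chosen once:
  25% of a
  mid-size peak is large enough to be learnable yet small against the
  baseline, and the package's checks rest on recovery properties, not on
  matching any particular accuracy level.
* **Noise**: one unit-mean log-normal factor per spectrum on the peak
  block and one on the baseline (`amplitude_cv = 0.1`, i.e. ~10%
  within-class variation standing in for patient/core heterogeneity), plus
  additive Gaussian shot/read noise (`noise_sd = 2` against a 100-unit
  main peak).
* **Determinism**: the cohort seed fixes the structure; each spectrum's
  seed derives from the cohort seed and the spectrum's position in the
  enumeration, so equal designs give bit-identical cohorts and subsetting
  never changes retained spectra.

What the generator does **not** model: cosmic-ray spikes, detector
response, wavelength calibration drift, spatial correlation within a core
beyond the shared jitter factor, Mie scattering backgrounds, and the full
biochemical covariance of real tissue. Consequently, near-perfect
accuracies on synthetic cohorts validate the machinery — leakage-free
folds, frozen models, correct operating points — and say nothing about
clinical performance, which can only be measured on real tissue spectra
that this package does not require.

## Numerical choices and degenerate inputs

* FISTA runs at most 500 iterations to relative objective tolerance 1e-9;
  `fs_C → 0⁺` correctly empties the selection, and an entirely empty
  selection at every candidate `fs_C` aborts training with an explicit
  error.
* Rolling-ball windows truncate at the spectrum edges; the radius must be
  a positive integer smaller than the spectrum length; all-zero and
  constant spectra come back as pure baseline.
* Grouped folds fail loudly ("stratification failure") when any fold
  would miss a class on either side of its split, rather than silently
  degrading; with *g* positive patients, 5-fold cross-validation needs
  g ≥ 5.
* Axis mismatches on load are resolved by linear interpolation onto the
  manifest axis, never extrapolation; out-of-coverage files are an error.
* On-disk round-trips preserve metadata exactly and intensities to at
  least 6 significant digits (plain TSV, one file per spectrum).

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on reduced cohorts (single-digit patients per
class, a 5 cm⁻¹ axis) chosen so each test isolates one property. The
acceptance script simulates the emulated cohort compositions in full where
the claim is about them (272 → 1,088 spectra and the benign counterparts),
verifies feature recovery at 50 patients per class on the full 1,022-point
axis over 3 seeds, and runs the end-to-end three-cohort study at
`scale = 0.34` of the full patient counts — the smallest scale at which
every contrast retains at least 5 positive patients for patient-grouped
5-fold cross-validation, which keeps the full run deterministic in
structure and fast without changing the generator's per-spectrum
conditions.

## Known limitations

* The L1 linear SVM uses the squared hinge (differentiable, standard in
  coordinate-descent solvers for this penalty); an exact-hinge variant
  could select marginally different feature sets.
* Effect sizes, lymphocyte compositions, and the rolling-ball radius are
  package choices, as documented above.
* Synthetic IDC-P cores always split acquisitions evenly between the
  lesion and adjacent cancer; real cores vary in how many acquisitions
  hit each region.
* Real cohorts contain per-core spectrum totals that are not multiples of
  4 (extra acquisitions on lesion-rich cores); the simulator keeps a strict
  4-acquisitions-per-core protocol and the per-class patient counts
  instead.
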