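# ramanidc

Diagnostic classification of prostate tissue from confocal Raman
micro-spectra, with a focus on intraductal carcinoma of the prostate
(IDC-P) — an aggressive lesion that pathologists struggle to separate from
high-grade prostatic intraepithelial neoplasia (HGPIN) because no reliable
molecular biomarker is in clinical use. The package is written for
spectroscopists and computational pathologists who want a tested,
reproducible implementation of the full analysis chain, runnable end to end
on simulated cohorts without any external data.

## What it implements

Spectra are intensities over Raman shifts 602–1,726 cm⁻¹ (~1.1 cm⁻¹
resolution, >1,000 features), acquired 4 times per tissue-microarray core.
The pipeline is:

1. **Background removal** — aluminum-substrate and tissue-fluorescence
   baseline estimated by the 1-D rolling-ball algorithm (grayscale erosion,
   dilation, boxcar smoothing; default half-width 50 grid points) and
   subtracted.
2. **Standardization** — each wavenumber feature centered to mean 0 and
   unit variance, with statistics fitted on the training cohort only.
3. **Feature selection** — a linear SVM with squared-hinge loss and an L1
   weight penalty,
   min‖w‖₁ + C Σᵢ max(0, 1 − yᵢ(xᵢᵀw + b))²,
   keeps only wavenumbers with non-zero weight (C ∈ [0.05, 0.5]).
4. **Classification** — a Gaussian-kernel SVM, K(x, x′) = exp(−γ‖x − x′‖²),
   on the selected features; C ∈ [0.1, 1000], γ ∈ [10⁻⁴, 10⁻¹] chosen by
   grid search with patient-grouped, class-stratified 5-fold
   cross-validation (selection and standardization refitted inside each
   fold).
5. **Independent testing** — the winning model is refitted on the complete
   training cohort, frozen, and applied to two testing cohorts; the
   decision threshold is the ROC point with minimal distance to the
   upper-left corner (0, 1).
6. **Interpretation** — selected wavenumbers are assigned to a packaged
   reference of discriminative prostate Raman bands (DNA/RNA ring modes,
   amide I/III, phenylalanine, tyrosine, …).

Four contrasts are supported: lymphocyte vs. cancer, benign vs. cancer
(spectrum level), IDC-P vs. cancer, and HGPIN vs. IDC-P (IDC-P and its
adjacent cancer pooled and averaged per core).

A synthetic-cohort module simulates three-institution tissue-microarray
studies — fluorescence/substrate baselines, shared tissue peaks,
class-dependent amplitude shifts at the reference wavenumbers, per-spectrum
jitter and shot noise — so every stage runs and is tested offline.

## Worked example

```r
library(ramanidc)

cohorts <- simulate_study_cohorts(seed = 1, scale = 0.34)
training <- preprocess_cohort(cohorts$training)   # rolling-ball correction

fit <- grid_search_train(training, contrast_spec("benign_vs_cancer"),
                         seed = 1)
fit
#> <raman_classifier> contrast benign_vs_cancer
#>   fs_C = 0.35, svm_C = 0.1, gamma = 0.0001; 239 features selected
#>   CV accuracy 100.0 +/- 0.0%; decision threshold 0.7896

ev <- evaluate_classifier(fit, preprocess_cohort(cohorts$test1))
ev$metrics
#> # A tibble: 1 x 9
#>   contrast         cohort row_unit     n accuracy sensitivity specificity
#>   <chr>            <chr>  <chr>    <int>    <dbl>       <dbl>       <dbl>
#> 1 benign_vs_cancer test1  spectrum   272      100         100         100
#> # i 2 more variables: auc <dbl>, threshold <dbl>

head(assign_peaks(fit$selection), 3)
#> # A tibble: 3 x 10
#>   selected_cm1 matched distance_cm1 contrast         feature_cm1 center_lo_cm1
#>          <dbl> <lgl>          <dbl> <chr>            <chr>               <dbl>
#> 1         668  FALSE          51    <NA>             <NA>                   NA
#> 2         716. TRUE            2.60 benign_vs_cancer 720/733               719
#> 3         718. TRUE            1.5  benign_vs_cancer 720/733               719
```

The cross-validated accuracy is the mean over 5 patient-grouped folds (the
SD over folds is the modeling uncertainty); the testing row shows the
frozen model applied to an independently simulated cohort. Accuracies on
these synthetic cohorts are near-perfect because the generator's planted
class differences are cleaner than real tissue heterogeneity — the
simulation validates the machinery, not clinical performance.
`assign_peaks()` links each selected wavenumber to a reference band when
one lies within the tolerance (here the adenine/protein ring-breathing
band near 719–726 cm⁻¹); wavenumbers far from any reference band stay
unmatched.

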