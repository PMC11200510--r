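# ivimcad

IVIM-based parametric mapping and zonal classification for prostate
diffusion-weighted MRI.

Prostate cancer (PCa) and benign prostatic hyperplasia (BPH) both alter the
diffusion properties of prostate tissue, and conventional apparent diffusion
coefficient (ADC) maps conflate true tissue diffusion with capillary
perfusion. The intravoxel incoherent motion (IVIM) model separates the two:

    S(b) = S0 * ( f * exp(-b * D*) + (1 - f) * exp(-b * D) )

where `S0` is the unweighted signal, `f` the perfusion fraction, `D` the
tissue diffusion coefficient and `D*` (>= D) the pseudo-diffusion
coefficient of the microvascular compartment. This package is for
researchers who want a fully tested, self-contained implementation of the
resulting diagnostic pipeline:

1. **Phantom simulation** — zoned digital prostate phantoms (central zone /
   peripheral zone / lesion) with class-conditional IVIM tissue parameters
   and Rician noise, so every downstream stage is testable without clinical
   data (`phantomSpec()`, `generateCohort()`).
2. **Parameter estimation** — voxel-wise bounded Levenberg–Marquardt fitting
   of `(S0, f, D, D*)` with deterministic segmented initialization, plus ADC
   mapping with a continuity correction (`fitIvimCurve()`,
   `fitIvimVolume()`).
3. **Zonal features** — six histogram statistics per parameter per zone
   (`extractFeatures()`, `cohortFeatureTable()`).
4. **Model selection** — scaler → PCA → classifier pipelines (MLP, decision
   trees, random forests, boosting families, KNN) evaluated by stratified
   repeated cross-validation with a benchmark-style leaderboard
   (`crossValidate()`, `gridSearch()`).
5. **Metrics** — confusion-matrix metrics, mid-rank ROC-AUC, balanced
   accuracy, Dice and IoU (`confusionMetrics()`, `rocAuc()`, `diceIou()`).

I/O uses the standard interchange formats: NIfTI-1 volumes and masks,
FSL-style `.bval` text, CSV feature tables.

## Worked example

Simulate a small labelled cohort, fit IVIM maps, extract combined CZ+PZ
features and cross-validate a random forest:

```r
library(ivimcad)

spec <- phantomSpec(cohortSize = 20, nPositive = 10,
                    gridShape = c(32, 32, 4), lesionRadius = 3, seed = 7)
cohort <- generateCohort(spec)
maps <- cohortParameterMaps(cohort)
tab <- cohortFeatureTable(cohort, maps, modalityFeatureSpec("CZ+PZ"))

report <- crossValidate(tab,
  modelSpec("RFC", list(class_weight = "None", criterion = "Gini",
                        max_depth = 5, n_estimators = 100),
            scalerKind = "standardization", modality = "CZ+PZ", seed = 1),
  cvSpec(nFolds = 5, nRepeats = 10, seed = 2))
report
#> CVReport: RFC on CZ+PZ, 5x10 CV
#>   accuracy           92.50% +/- 11.573
#>   sensitivity        90.00% +/- 20.203
#>   specificity        95.00% +/- 15.152
#>   precision          96.67% +/- 10.102
#>   f1                 91.33% +/- 13.818
#>   roc_auc            93.00% +/- 16.004
#>   balanced_accuracy  92.50% +/- 11.573
```

Each line is the mean ± standard deviation over the 50 fold evaluations
(5 folds × 10 repeats). Balanced accuracy is the mean of sensitivity and
specificity — with 20 cases per cohort the per-fold test sets are tiny,
hence the large spreads; the defaults (`phantomSpec()` with no arguments)
run the full 80-case study. The decay of one voxel can be inspected with
`voxelCurve()` and fitted directly:

```r
fitIvimCurve(voxelCurve(cohort[[1]]@dwi, 16, 12, 2))
#> FitResult [converged] after 11 iterations, SSR = 3440.93
#> IVIMParams: S0 = 1038, f = 0.1854, D = 0.001292 mm^2/s, D* = 0.007541 mm^2/s
```

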