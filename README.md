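# rsmoteenn

Hybrid resampling and benchmarking for **small, severely imbalanced
multiclass tabular data**, built around heart-rate-variability (HRV)
feature panels used to classify autonomic-nervous-system (ANS) states.

Clinical HRV cohorts are tiny and lopsided: a few hundred records, most of
them in the "balanced" class, with the clinically interesting states
(sympathetic disorder, dysautonomia, vagal damage) contributing a handful
of rows each. Classifiers trained on such data learn the majority class.
`rsmoteenn` implements a refined SMOTE-ENN pipeline for this regime and the
evaluation tooling to measure whether it helped.

## The method

Features are z-scored, $z = (x - \mu)/\sigma$, then minority classes are
oversampled to the majority count by two interpolation moves between a seed
$x_i$ and one of its $k = 3$ same-class nearest neighbours $x_j$:

* **in-line**: $x_{\text{new}} = x_i + \lambda (x_j - x_i)$,
  $\lambda \sim \mathcal U[-1, 1]$ — on the line through the pair,
  extrapolating beyond the seed when $\lambda < 0$;
* **off-line**: $x_{\text{new}} = x_i + d\cos\theta\,(\cos\theta\,
  e_\parallel + \sin\theta\, e_\perp)$, $\theta \sim \mathcal
  U[-\pi/2, \pi/2]$ — on the sphere whose diameter is the $x_i$–$x_j$
  segment (so $(x_{\text{new}}{-}x_i) \cdot (x_{\text{new}}{-}x_j) = 0$,
  Thales' right angle), with $e_\perp$ an isotropic random unit vector
  orthogonal to the segment.

The augmented data are then cleaned by **refined ENN**: each row whose
label disagrees with the plurality vote of its 3 nearest neighbours is
flagged as boundary/noise, and all but a retained fraction (default 15%,
drawn per class) of the flagged rows are removed. Retaining part of the
boundary keeps genuine class-overlap structure and reduces overfitting;
applying the vote to *all* rows lets the majority class shrink during
cleaning.

Evaluation uses a stratified 80/20 split in a **leakage-safe** protocol
(resample the training partition only; a `paper_faithful` mode that
resamples before splitting is provided for comparison), then benchmarks
four classifiers — RBF-SVM ($C{=}10$, $\gamma{=}1$), a 1000-tree random
forest, a 256/128/64 batch-norm + dropout network, and 3-NN — reporting
confusion matrices, accuracy, macro precision/recall/F1, one-vs-rest
macro AUC, and cross-model permutation-importance mean ranks.

Because the clinical cohorts this method targets are not public, the
package ships a synthetic cohort generator (log-normal class-conditional
features with physiological correlation structure, exact spectral
identities TSP ≈ VLF+LF+HF and LF/HF = LF÷HF, and the imbalanced class
counts {63, 6, 9, 195, 12, 24, 12}) so the whole pipeline is testable end
to end. See `vignettes/refined-smote-enn.Rmd` for the full methods
account.

## Worked example

```r
library(rsmoteenn)

ds <- generate_cohort(cohort_config(seed = 7))
ds
#> <hrv_dataset> 321 samples x 9 features
#>   features: HR, SDNN, rmSSD, PNN50, VLF, LF, HF, TSP, LF.HF
#>   class counts: 1:63 2:6 3:9 4:195 5:12 6:24 7:12
#>   provenance: original:321

out <- run_protocol(ds, "leakage_safe",
                    split_spec(0.2, stratified = TRUE, seed = 1),
                    smote_config(seed = 2), enn_config(seed = 3))
out$result
#> <resample_result> mode = leakage_safe
#>  class original synthetic_added removed final
#>      1       50             106      11   145
#>      2        5             151       8   148
#>      3        7             149       1   155
#>      4      156               0      23   133
#>      5        9             147       2   154
#>      6       19             137       2   154
#>      7       10             146       2   154
#> total: 256 -> 1043 samples
```

The 256-row training partition is oversampled to the majority count per
class (note class 2: five originals, 151 synthetics), then ENN cleaning
removes label-inconsistent rows — including 23 from the majority class —
leaving 1043 training rows; the 65 test rows stay untouched originals.

```r
rep <- run_benchmark(out$train, out$test,
                     specs = list(classifier_spec("rf", seed = 4),
                                  classifier_spec("knn", seed = 4)),
                     importance_repeats = 10)
rep
#> <benchmark_report> 2 models, 7 classes
#>  model accuracy precision recall    f1 macro_auc
#>     rf    0.815     0.636  0.795 0.690     0.897
#>    knn    0.769     0.570  0.709 0.618     0.875
```

Accuracy is the fraction of the 65 test rows classified correctly; the
macro columns average per-class one-vs-rest metrics with equal class
weight, so they are sensitive to the tiny classes; `macro_auc` averages
per-class ROC AUCs. The report also holds per-model confusion matrices,
ROC curves, and permutation feature importances with cross-model mean
ranks.

A thin command-line wrapper over these functions is at
`inst/cli/rsmoteenn.R` (`generate`, `resample`, `benchmark` subcommands).

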