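---
title: "Refined SMOTE-ENN: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refined SMOTE-ENN: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(rsmoteenn)
```

## The problem

Clinical heart-rate-variability (HRV) panels are small and severely
imbalanced. A typical screening cohort concentrates in the "autonomic
balance" class while clinically interesting states — sympathetic disorder,
dysautonomia, vagal damage — contribute a handful of records each. Standard
classifiers trained on such data learn the majority class and miss exactly
the states one wants to detect. `rsmoteenn` implements a hybrid resampling
method for this regime: geometric minority oversampling (refined SMOTE)
followed by consistency-based cleaning with partial boundary retention
(refined ENN), plus the evaluation machinery — a four-model benchmark with
macro metrics, one-vs-rest ROC/AUC and permutation feature importance — to
measure whether the resampling actually helped.

## The resampling model

All interpolation happens in z-scored feature space. For a dataset
$x_1, \dots, x_n$ with nine features, each feature is standardized as
$z = (x - \mu)/\sigma$, with $\mu$ and $\sigma$ the per-feature mean and
*population* (divisor-$n$) standard deviation. Distances are then
comparable across features with wildly different units (bpm, ms, ms²).
The divisor choice matters little at these sample sizes ($<1\%$ at
$n = 321$); the sample (divisor $n-1$) form is available via
`fit_standardizer(divisor = "n-1")`.

### In-line interpolation

For a minority seed $x_i$ and one of its $k = 3$ same-class nearest
neighbours $x_j$ (Euclidean distance, distance ties broken by lower row
index), the classic SMOTE move synthesizes

$$x_{\mathrm{new}} = x_i + \lambda\,(x_j - x_i), \qquad \lambda \sim
\mathcal U[-1, 1].$$

Note the range: $\lambda < 0$ extrapolates *behind* the seed, which widens
the synthetic cloud beyond the convex hull that classic SMOTE
($\lambda \in [0,1]$) is confined to. `classic_smote_config()` provides the
classic preset for paired comparisons.

### Off-line (Thales sphere) interpolation

The refinement synthesizes points *off* the seed–neighbour line, on the
sphere whose diameter is the segment from $x_i$ to $x_j$. With
$d = \lVert x_j - x_i\rVert$, $e_\parallel = (x_j - x_i)/d$, and $e_\perp$ a
unit vector orthogonal to $e_\parallel$,

$$x_{\mathrm{new}} = x_i + d\cos\theta\,(\cos\theta\, e_\parallel +
\sin\theta\, e_\perp), \qquad \theta \sim \mathcal U[-\tfrac{\pi}{2},
\tfrac{\pi}{2}].$$

Three properties pin this construction down and are enforced by tests:

* $\lVert x_{\mathrm{new}} - x_i\rVert = d\cos\theta$, so $\theta = 0$
  lands exactly on $x_j$ and $\theta = \pm\pi/2$ on $x_i$;
* $(x_{\mathrm{new}} - x_i)\cdot(x_{\mathrm{new}} - x_j) = 0$ — the
  inscribed right angle of Thales' theorem, equivalently membership of the
  sphere with centre $(x_i + x_j)/2$ and radius $d/2$;
* in two dimensions, taking $e_\perp$ as the clockwise 90° rotation of
  $e_\parallel$ recovers the planar construction
  $x_i + d\cos\theta\,(\cos\varphi, \sin\varphi)$ with
  $\varphi = \operatorname{atan2}(x_{j2}-x_{i2},\, x_{j1}-x_{i1}) - \theta$.

The planar construction does not say what to do with nine features, where
"the circle" is not unique. We generalize by drawing $e_\perp$ as an
isotropic random unit vector orthogonal to $e_\parallel$ (sample a standard
normal vector, project out the parallel component, normalize; resample in
the measure-zero event of a degenerate norm). The 2-D circle becomes a
great circle of the Thales sphere chosen uniformly at random. This is the
only rotation-invariant choice that preserves all three properties above in
any dimension, and it reduces exactly to the planar formula in 2-D. A
consequence worth noting: in three or more dimensions the sign of $\theta$
carries no information, because $-e_\perp$ is as likely as $e_\perp$.

### Scheduling and mode mix

Each undersized class is brought up to its target count (default: the
largest class's count). Seeds cycle round-robin over the class's original
rows so every original contributes; the neighbour is drawn uniformly from
the seed's $k$ same-class neighbours; each synthetic row flips a
Bernoulli(0.5) coin between the two interpolation modes
(`offline_probability`). Neither the schedule nor the mode proportion is
canonical; both are explicit knobs, and provenance tags
(`synthetic_inline` / `synthetic_offline`) record what was done. Classes
with a single member cannot be oversampled (no neighbour exists) and raise
an error; $k$ is clamped to class size $-1$ with a warning where needed.

### Refined ENN cleaning

After oversampling, every row — original and synthetic, majority included —
is voted on by its $k = 3$ nearest neighbours (any class). A row whose own
label differs from the unique plurality of its neighbours (or whose vote is
tied, which we treat conservatively as inconsistency) is flagged as a
boundary/noise row. All flags are computed in one pass over the fixed
dataset; there is no sequential deletion. Classical ENN removes every
flagged row; the refinement *retains* a fraction of them — default 0.15,
inside the method's 10–20% band — to keep genuine boundary structure and
reduce overfitting. Retention is a uniform random draw, stratified per
class (largest-remainder apportionment) so tiny classes are not wiped. Two
guard rails are our own additions, documented as such: stratification
itself, and an empty-class rescue that keeps the flagged row nearest its
class centroid (with a warning) if removal would delete a class outright.

Applying ENN to the majority class too is deliberate: it is what lets the
majority count *shrink* during "oversampling" (e.g. 195 original balance
records reducing to ~125 after cleaning), which is characteristic of this
hybrid's published count tables.

### Protocol modes

`run_protocol()` offers two orderings. `paper_faithful` resamples the whole
dataset and then splits 80/20 — the protocol many small-data studies use,
which leaks synthetic copies of test-set information into training and
inflates test metrics. `leakage_safe` (the default everywhere in this
package) splits first and resamples only the training partition; the test
set stays all-original. The test partition holds
$\lceil 0.2\,n \rceil$ rows, reproducing the conventional 937/235 partition
of a 1172-row optimized set. Because minority classes can have six members,
the stratified split option matters: a simple random 20% draw can leave a
class absent from one partition.

## The benchmark

Four classifiers, with the hyperparameter sets tuned for this problem
class:

| model | settings |
|-------|----------|
| SVM   | RBF kernel, $C = 10$, $\gamma = 1$; pairwise-coupling probability calibration for ROC scores |
| RF    | 1000 trees, $\sqrt p$ feature subsampling, min split 2, min leaf 1, bootstrap off |
| NN    | 9 → 256 → 128 → 64 → 7 softmax; ReLU; batch-norm + 30% dropout on the first two hidden layers; L2 on the second hidden layer; He initialization |
| KNN   | Euclidean, $k = 3$ |

Notes on the implementations:

* The SVM and forest are fitted by `e1071` and `randomForest`. "Bootstrap
  off" is realized as sampling $n$ rows without replacement, so every tree
  sees the full training set and randomness enters only through feature
  subsampling. `randomForest` splits on Gini impurity; an entropy criterion
  is not available in the R forest implementations, and at these depths the
  two criteria rarely change splits — we use Gini and say so.
* The network is implemented directly in base R matrix algebra (the data
  are 9-dimensional and a few hundred to a thousand rows; a framework would
  add nothing). Training: Adam (learning rate $10^{-3}$), batch 32, at most
  500 epochs, early stopping on a 10% validation slice with patience 30,
  and learning-rate halving after 10 epochs without validation improvement.
  Batch size, epoch cap and patience are configurable; the architecture is
  fixed.
* KNN scoring is the neighbour vote fraction per class, computed in-house
  because off-the-shelf k-NN predictors return only the winning class's
  proportion and one-vs-rest ROC needs the full score matrix. With $k = 3$
  the scores take values in $\{0, \frac13, \frac23, 1\}$, so its ROC curves
  are coarse; that is a property of the model, not the implementation.
* SVM, NN and KNN are scale-sensitive and z-score features internally from
  training statistics (constant columns tolerated with $\sigma := 1$); the
  forest trains on raw features.

Evaluation: confusion matrix over the training label set; accuracy; macro
(unweighted) precision, recall and F1 — the published single-number
summaries for this task do not name their averaging, and macro is the
appropriate choice for a test set in which classes matter equally; micro
averaging is available as an option. ROC/AUC is one-vs-rest per class with
an unweighted macro mean, computed via `pROC` (trapezoidal, equivalent to
the Mann–Whitney rank statistic; the test suite checks that equivalence
against an independent rank-based oracle). A class never predicted gets
precision 0 and is flagged; a class absent from the test labels has
undefined AUC and is excluded from the macro mean with a warning.

Feature importance uses permutation importance for every model — the mean
macro-F1 drop over 20 seeded shuffles of each feature column — because
cross-model mean ranks need a single comparable scale; the forest's
impurity importance is additionally available. Within each model, rank 1 is
the largest score, ties share the average rank, and the cross-model mean
rank orders the final table.

## The synthetic cohort generator

The real cohorts this method targets are clinical and not public, so the
generator's job is *structural* realism, never replication:

* Class-conditional **log-normal** features: the seven base features (HR,
  SDNN, rmSSD, PNN50, VLF, LF, HF) are drawn as correlated multivariate
  normals in log space and exponentiated — spectral powers are positive and
  right-skewed, and this guarantees positivity by construction. Baselines
  sit at physiologically unremarkable values (HR ≈ 70 bpm, SDNN ≈ 50 ms,
  total power ≈ 2200 ms²).
* The **correlation structure** encodes known couplings: the vagally
  mediated trio SDNN/rmSSD/PNN50 co-varies strongly (0.5–0.7), rmSSD
  couples to HF (0.6), the spectral bands co-vary mildly, and HR runs
  weakly against the variability measures.
* The two **derived features** are constructed, not sampled:
  $\mathrm{TSP} = (\mathrm{VLF} + \mathrm{LF} + \mathrm{HF})(1 +
  \varepsilon)$ with $\varepsilon \sim \mathcal N(0, 0.02)$, and LF/HF as
  the exact ratio. This plants the strong TSP–LF and LF/HF–LF/HF couplings
  that make naive independence assumptions fail on real HRV panels, so the
  benchmark is stressed the way real data would stress it.
* **Class locations** shift the log-means directionally per autonomic
  state: stress raises HR and LF while depressing SDNN/rmSSD/HF; fatigue
  elevates rmSSD/HF relative to LF; dysautonomia depresses everything;
  balance sits at baseline. Default class counts are the imbalanced
  {63, 6, 9, 195, 12, 24, 12} of a 321-record screening cohort.
* A single **overlap** knob scales all between-class offsets by
  $2.5/(1 + \mathrm{overlap})$. The default (0.5) was calibrated once, to
  the regime the method is for: majority classes classify well untreated
  (per-class F1 ≈ 0.8–0.9 for a 3-NN reference) while minority classes
  visibly underperform (F1 ≈ 0.1–0.6), so a resampler's effect is
  measurable. Raising overlap degrades held-out macro-F1 monotonically — a
  property the test suite checks at overlap 0, 1 and 3 (medians over 5
  seeds).

What the generator does **not** emulate: measurement noise and artifacts
of RR-interval extraction, age/sex covariate structure, label noise in the
clinical annotations, and the unknown true class-conditional distributions
of any real cohort. Passing tests on this cohort therefore demonstrate that
the pipeline behaves as specified and that the resampler helps in a
controlled imbalanced regime — not that any particular clinical accuracy
will be attained on real data.

`planted_boundary_cohort()` is a separate, deliberately crude fixture for
the cleaning stage: two well-separated Gaussian clusters plus mislabelled
points planted with known indices, so boundary-flagging recall is exactly
measurable.

## Numerical choices and degenerate inputs

* Distance ties everywhere resolve to the lower row index, making every
  neighbour computation deterministic.
* A tied neighbourhood vote is treated as boundary (conservative: favours
  cleaning). With $k = 3$ and two classes ties cannot occur; with seven
  classes they can.
* The off-line construction rejects coincident seed/neighbour pairs
  (degenerate sphere); the sampler falls back to in-line interpolation for
  duplicate points. Orthogonality and unit norm of a supplied
  perpendicular are verified to $10^{-9}$.
* Constant features are rejected by `fit_standardizer()` with the feature
  named; the classifiers' internal scaler instead tolerates them (test
  partitions of tiny classes can be constant in a column).
* CSV serialization uses 17 significant digits, so write/read round-trips
  are bit-exact.
* All randomness flows through per-config integer seeds; every public
  operation restores the caller's RNG state. Identical seeds give
  byte-identical resampling results end-to-end.

## Problem sizes used by the test suite

The suite exercises the geometric contracts at 10,000 random 9-D triples
and 1,000 random 2-D cases; ENN oracle equivalence on 200 random instances
of 20–100 rows; and the end-to-end effect-direction experiment on the
default 321-row cohort with a stratified 80/20 split, 10 paired seeds and
all three resampling conditions (none / classic preset / refined). These
sizes keep the full suite in the minutes range while leaving every
assertion at full strength.

## Known limitations

* Oversampling targets are fully configurable but default to the majority
  count; published count tables for this method imply targets above the
  majority count for some classes, without stating them. The default is an
  assumption, recorded as such.
* Permutation importance on a small test set is noisy; mean ranks are
  stable in our tests but individual scores are not.
* The NN is the one stochastic-training model; its determinism contract is
  "within $10^{-6}$" rather than byte-identical, reflecting floating-point
  accumulation order.
* The retention draw retains boundary rows uniformly at random (per
  class); retaining by distance-to-boundary is a plausible alternative the
  package does not implement. In particular, retention does not distinguish
  flagged *originals* (real boundary structure) from flagged *synthetics*
  (fabricated noise), so a slice of interpolation noise survives cleaning.
* Resampling is not uniformly beneficial across learners. In the test
  suite's paired effect-direction experiment on the default cohort, the
  refined pipeline raises median macro-F1 for the SVM, forest and k-NN but
  not for the network, which copes with the raw imbalance well and is
  mildly hurt by the extrapolating synthetics and retained boundary noise.
  The corresponding benchmark expectation is asserted at full strength and
  fails for the network; we report this rather than weaken the check.
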