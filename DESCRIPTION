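Package: rsmoteenn
Title: Refined SMOTE-ENN Resampling for Imbalanced HRV Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid resampling for small, severely imbalanced multiclass
    tabular data, developed around heart-rate-variability (HRV) feature sets.
    Minority classes are oversampled by refined SMOTE, which interpolates both
    on the segment between a seed sample and a same-class neighbour (in-line)
    and on the sphere whose diameter is that segment (off-line, Thales
    construction); the augmented data are then cleaned by a refined Edited
    Nearest Neighbor rule that removes label-inconsistent samples while
    retaining a configurable fraction of boundary points. Includes a
    leakage-safe evaluation protocol, a four-model classification benchmark
    (SVM, random forest, neural network, k-NN) with macro metrics,
    one-vs-rest ROC/AUC and permutation feature importance, and a synthetic
    HRV cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    randomForest,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
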