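#' Classifier specification
#'
#' One of the four benchmark models with its tuned hyperparameters:
#' \describe{
#'   \item{svm}{RBF-kernel support vector machine, `C = 10`, `gamma = 1`,
#'     with pairwise-coupling probability calibration for ROC scoring.}
#'   \item{rf}{Random forest: 1000 trees, `sqrt` feature subsampling,
#'     minimum split 2, minimum leaf 1, bootstrap off (every tree sees the
#'     full training set; randomness enters through feature subsampling).
#'     Split criterion is Gini impurity.}
#'   \item{nn}{Fully connected network 256/128/64, ReLU, batch
#'     normalization and 30% dropout on the first two hidden layers, L2 on
#'     the second hidden layer, softmax output, He initialization; trained
#'     with Adam, early stopping on a 10% validation slice and
#'     learning-rate halving on plateaus.}
#'   \item{knn}{k-nearest neighbours, Euclidean distance, `k = 3`.}
#' }
#'
#' @param kind One of `"svm"`, `"rf"`, `"nn"`, `"knn"`.
#' @param hyperparameters Named list overriding the defaults above.
#' @param seed Integer seed for any randomness in training.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm", "rf", "nn", "knn"),
                            hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    svm = list(C = 10, gamma = 1, kernel = "radial"),
    rf = list(n_trees = 1000L, max_features = "sqrt",
              min_samples_split = 2L, min_samples_leaf = 1L,
              bootstrap = FALSE),
    nn = list(hidden = c(256L, 128L, 64L), dropout = 0.3, l2 = 1e-4,
              lr = 1e-3, batch_size = 32L, max_epochs = 500L,
              patience = 30L, lr_patience = 10L, val_fraction = 0.1),
    knn = list(k = 3L))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(kind = kind, hyperparameters = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

# Internal feature scaler for the distance/gradient-based models (svm, nn,
# knn). Unlike fit_standardizer() it tolerates constant columns (sigma set
# to 1) so degenerate toy inputs still train.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sigma <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sigma[sigma == 0] <- 1
  list(mu = mu, sigma = sigma)
}

apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$mu), 2, sc$sigma, "/")
}

#' Train a benchmark classifier
#'
#' Fits the model described by `spec` on a training dataset. For the
#' scale-sensitive models (SVM, NN, KNN) features are z-scored internally
#' using statistics of the training data; the random forest is
#' scale-invariant and trains on raw features. Training is deterministic
#' given `spec$seed` (exactly for rf/knn/svm, to numerical precision for
#' the network).
#'
#' @param spec A [classifier_spec()].
#' @param train A validated `hrv_dataset` with at least 2 classes.
#' @return Object of class `hrv_classifier`, supporting
#'   [predict_classifier()] and [score_classifier()].
#' @export
train_classifier <- function(spec, train) {
  stopifnot(inherits(spec, "classifier_spec"))
  validate_hrv_dataset(train)
  classes <- sort(unique(train$labels))
  if (length(classes) < 2) stop("training set has fewer than 2 classes")
  hp <- spec$hyperparameters
  X <- train$features
  y <- factor(train$labels, levels = classes)
  scaler <- NULL
  model <- switch(spec$kind,
    svm = {
      scaler <- fit_scaler(X)
      with_seed(spec$seed,
        e1071::svm(x = apply_scaler(X, scaler), y = y, scale = FALSE,
                   kernel = hp$kernel, cost = hp$C, gamma = hp$gamma,
                   probability = TRUE))
    },
    rf = {
      mtry <- if (identical(hp$max_features, "sqrt"))
        max(1L, floor(sqrt(ncol(X)))) else as.integer(hp$max_features)
      with_seed(spec$seed,
        randomForest::randomForest(
          x = X, y = y, ntree = hp$n_trees, mtry = mtry,
          nodesize = hp$min_samples_leaf, replace = hp$bootstrap,
          sampsize = if (hp$bootstrap) nrow(X) else nrow(X)))
    },
    nn = {
      scaler <- fit_scaler(X)
      mlp_train(apply_scaler(X, scaler), as.integer(y), length(classes),
                hidden = hp$hidden, dropout = hp$dropout, l2 = hp$l2,
                lr = hp$lr, batch_size = hp$batch_size,
                max_epochs = hp$max_epochs, patience = hp$patience,
                lr_patience = hp$lr_patience, val_fraction = hp$val_fraction,
                seed = spec$seed)
    },
    knn = {
      scaler <- fit_scaler(X)
      list(X = apply_scaler(X, scaler), y = as.integer(y), k = hp$k)
    })
  structure(list(spec = spec, kind = spec$kind, model = model,
                 scaler = scaler, classes = classes,
                 feature_names = train$feature_names),
            class = "hrv_classifier")
}

#' @export
print.hrv_classifier <- function(x, ...) {
  cat("<hrv_classifier> kind =", x$kind, "| classes:",
      paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Class-probability scores from a fitted classifier
#'
#' @param handle An `hrv_classifier` from [train_classifier()].
#' @param ds A validated `hrv_dataset` with matching feature count.
#' @return Numeric matrix, one column per training class (named by label),
#'   rows summing to 1.
#' @export
score_classifier <- function(handle, ds) {
  stopifnot(inherits(handle, "hrv_classifier"))
  X <- ds$features
  cls <- as.character(handle$classes)
  P <- switch(handle$kind,
    svm = {
      pr <- stats::predict(handle$model, apply_scaler(X, handle$scaler),
                           probability = TRUE)
      attr(pr, "probabilities")[, cls, drop = FALSE]
    },
    rf = stats::predict(handle$model, X, type = "prob")[, cls, drop = FALSE],
    nn = {
      P <- mlp_predict_proba(handle$model, apply_scaler(X, handle$scaler))
      colnames(P) <- cls
      P
    },
    knn = knn_vote_scores(handle$model, apply_scaler(X, handle$scaler),
                          length(cls), cls))
  rownames(P) <- NULL
  P
}

#' Predict class labels
#'
#' @inheritParams score_classifier
#' @return Integer label vector. KNN predicts the plurality vote of the 3
#'   nearest training rows (distance ties broken by lower training index;
#'   vote ties by the class of the nearest neighbour among the tied
#'   classes); the other models predict their highest-scoring class.
#' @export
predict_classifier <- function(handle, ds) {
  stopifnot(inherits(handle, "hrv_classifier"))
  if (handle$kind == "knn") {
    Z <- apply_scaler(ds$features, handle$scaler)
    return(knn_predict_labels(handle$model, Z, handle$classes))
  }
  P <- score_classifier(handle, ds)
  handle$classes[max.col(P, ties.method = "first")]
}

# k-NN vote fractions per class (rows of Z are queries).
knn_vote_scores <- function(model, Z, n_classes, class_names) {
  k <- model$k
  P <- matrix(0, nrow(Z), n_classes, dimnames = list(NULL, class_names))
  for (i in seq_len(nrow(Z))) {
    d <- sqrt(colSums((t(model$X) - Z[i, ])^2))
    nb <- order(d, seq_along(d))[seq_len(k)]
    tab <- tabulate(model$y[nb], nbins = n_classes)
    P[i, ] <- tab / k
  }
  P
}

knn_predict_labels <- function(model, Z, classes) {
  k <- model$k
  out <- integer(nrow(Z))
  for (i in seq_len(nrow(Z))) {
    d <- sqrt(colSums((t(model$X) - Z[i, ])^2))
    nb <- order(d, seq_along(d))[seq_len(k)]
    votes <- model$y[nb]
    tab <- tabulate(votes, nbins = length(classes))
    top <- which(tab == max(tab))
    win <- if (length(top) == 1) top else votes[match(TRUE, votes %in% top)]
    out[i] <- classes[win]
  }
  out
}

#' Feature importance of a fitted classifier
#'
#' Permutation importance (default, available for every model): the mean
#' drop in macro F1 on `data` over `repeats` independent shuffles of each
#' feature column, seeded. Impurity importance (random forest only): the
#' forest's mean decrease in node impurity at splits on the feature.
#'
#' @param handle An `hrv_classifier`.
#' @param data A validated `hrv_dataset` to measure importance on.
#' @param method `"permutation"` (default) or `"impurity"` (rf only).
#' @param seed Integer seed for the shuffles.
#' @param repeats Number of shuffles per feature (default 20).
#' @return Named numeric vector of per-feature scores (larger = more
#'   important).
#' @export
feature_importance <- function(handle, data, method = c("permutation",
                                                        "impurity"),
                               seed = 1L, repeats = 20L) {
  method <- match.arg(method)
  stopifnot(inherits(handle, "hrv_classifier"))
  if (method == "impurity") {
    if (handle$kind != "rf")
      stop("impurity importance is only defined for the random forest")
    imp <- randomForest::importance(handle$model)[, 1]
    names(imp) <- handle$feature_names
    return(imp)
  }
  validate_hrv_dataset(data)
  label_set <- handle$classes
  base_f1 <- metrics_from_confusion(
    confusion_matrix(data$labels, predict_classifier(handle, data),
                     label_set))$f1
  p <- ncol(data$features)
  n <- n_samples(data)
  with_seed(seed, {
    drops <- vapply(seq_len(p), function(j) {
      mean(vapply(seq_len(repeats), function(r) {
        perm <- data
        perm$features[, j] <- perm$features[sample.int(n), j]
        f1 <- metrics_from_confusion(
          confusion_matrix(perm$labels, predict_classifier(handle, perm),
                           label_set))$f1
        base_f1 - f1
      }, numeric(1)))
    }, numeric(1))
    stats::setNames(drops, data$feature_names)
  })
}

#' Run the four-model classification benchmark
#'
#' Trains every spec on `train`, evaluates on `test`, and assembles a
#' report holding, per model: the confusion matrix over the training label
#' set, accuracy and macro precision/recall/F1, per-class and macro
#' one-vs-rest AUC, and (optionally) permutation feature importances; plus
#' the cross-model per-feature mean ranks.
#'
#' @param train,test Validated `hrv_dataset`s with identical schema.
#' @param specs List of [classifier_spec()]s; default all four models.
#' @param compute_importance Compute permutation importances and mean ranks
#'   (default `TRUE`).
#' @param importance_repeats Shuffles per feature (default 20).
#' @param importance_seed Seed for the permutation draws.
#' @return Object of class `benchmark_report`: `models` (named list with
#'   `confusion`, `metrics`, `roc`, `importance`), `metrics_table`
#'   (data.frame), and `importance` (`ranks` + `mean_rank`) when computed.
#' @export
run_benchmark <- function(train, test,
                          specs = lapply(c("svm", "rf", "nn", "knn"),
                                         classifier_spec),
                          compute_importance = TRUE,
                          importance_repeats = 20L, importance_seed = 1L) {
  validate_hrv_dataset(train); validate_hrv_dataset(test)
  if (!identical(train$feature_names, test$feature_names))
    stop("train and test feature schemas differ")
  label_set <- sort(unique(train$labels))
  models <- list()
  for (spec in specs) {
    handle <- train_classifier(spec, train)
    pred <- predict_classifier(handle, test)
    scores <- score_classifier(handle, test)
    cm <- confusion_matrix(test$labels, pred, label_set)
    met <- metrics_from_confusion(cm)
    roc <- roc_auc_ovr(test$labels, scores, label_set)
    imp <- if (compute_importance)
      feature_importance(handle, test, "permutation",
                         seed = importance_seed,
                         repeats = importance_repeats) else NULL
    models[[spec$kind]] <- list(spec = spec, handle = handle, confusion = cm,
                                metrics = met, roc = roc, importance = imp)
  }
  metrics_table <- do.call(rbind, lapply(names(models), function(m) {
    met <- models[[m]]$metrics
    data.frame(model = m, accuracy = met$accuracy, precision = met$precision,
               recall = met$recall, f1 = met$f1,
               macro_auc = models[[m]]$roc$macro_auc)
  }))
  importance <- if (compute_importance)
    rank_and_mean_rank(lapply(models, `[[`, "importance")) else NULL
  structure(list(models = models, metrics_table = metrics_table,
                 importance = importance, label_set = label_set),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> ", length(x$models), " models, ",
      length(x$label_set), " classes\n", sep = "")
  tab <- x$metrics_table
  tab[-1] <- lapply(tab[-1], round, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$importance)) {
    cat("feature mean ranks:\n")
    print(x$importance$mean_rank, row.names = FALSE)
  }
  invisible(x)
}
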