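# Linearly separable 2-class toy every model should master.
separable_toy <- function(n_per_class = 30, seed = 1) {
  two_cluster_dataset(n_per_class = n_per_class, p = 9, separation = 30,
                      seed = seed)
}

test_that("all four models reach 100% training accuracy on a separable toy", {
  ds <- separable_toy(seed = 4)
  for (kind in c("svm", "rf", "nn", "knn")) {
    spec <- classifier_spec(kind, seed = 2)
    if (kind == "nn")
      spec <- classifier_spec("nn", list(max_epochs = 60L), seed = 2)
    h <- train_classifier(spec, ds)
    expect_identical(predict_classifier(h, ds), ds$labels,
                     label = paste(kind, "training predictions"))
  }
})

test_that("knn predicts the shared label of the 3 nearest training rows", {
  train <- hrv_dataset(cbind(c(0, 0.1, 0.2, 10, 10.1, 10.2)),
                       c(1L, 1L, 1L, 2L, 2L, 2L))
  h <- train_classifier(classifier_spec("knn"), train)
  query <- hrv_dataset(cbind(c(0.05, 9.9)), c(1L, 1L), label_set = 1:2)
  expect_identical(predict_classifier(h, query), c(1L, 2L))
  s <- score_classifier(h, query)
  expect_equal(unname(s[1, ]), c(1, 0))
  expect_equal(rowSums(s), c(1, 1))
})

test_that("probability scores are simplex rows aligned with the class set", {
  ds <- generate_cohort(cohort_config(seed = 12))
  parts <- split_train_test(ds, split_spec(0.2, stratified = TRUE, seed = 3))
  for (kind in c("svm", "rf", "knn")) {
    h <- train_classifier(classifier_spec(kind, seed = 5), parts$train)
    P <- score_classifier(h, parts$test)
    expect_identical(colnames(P), as.character(1:7))
    expect_equal(unname(rowSums(P)), rep(1, n_samples(parts$test)),
                 tolerance = 1e-6)
    expect_true(all(P >= 0))
  }
})

test_that("training is deterministic given spec, seed and data", {
  ds <- separable_toy(n_per_class = 20, seed = 9)
  test <- separable_toy(n_per_class = 10, seed = 10)
  for (kind in c("rf", "knn", "svm")) {
    h1 <- train_classifier(classifier_spec(kind, seed = 7), ds)
    h2 <- train_classifier(classifier_spec(kind, seed = 7), ds)
    expect_identical(score_classifier(h1, test), score_classifier(h2, test),
                     label = paste(kind, "scores"))
  }
  spec_nn <- classifier_spec("nn", list(max_epochs = 30L), seed = 7)
  n1 <- train_classifier(spec_nn, ds)
  n2 <- train_classifier(spec_nn, ds)
  expect_equal(score_classifier(n1, test), score_classifier(n2, test),
               tolerance = 1e-6)
})

test_that("the network fits its stated architecture", {
  ds <- separable_toy(n_per_class = 15, seed = 2)
  h <- train_classifier(classifier_spec("nn", list(max_epochs = 5L),
                                        seed = 1), ds)
  p <- h$model$params
  expect_identical(dim(p$W1), c(9L, 256L))
  expect_identical(dim(p$W2), c(256L, 128L))
  expect_identical(dim(p$W3), c(128L, 64L))
  expect_identical(dim(p$W4), c(64L, 2L))
  expect_length(p$gamma1, 256L)  # batch-norm on hidden layers 1 and 2
  expect_length(p$gamma2, 128L)
})

test_that("permutation importance finds the label-determining feature", {
  # feature 1 carries all the signal; feature 10 is pure noise
  rsmoteenn:::with_seed(31, {
    n <- 120
    x1 <- c(rnorm(n / 2, 0, 0.4), rnorm(n / 2, 4, 0.4))
    X <- cbind(x1, matrix(rnorm(n * 9), n, 10 - 1))
    ds <- hrv_dataset(X, rep(1:2, each = n / 2),
                      feature_names = paste0("V", 1:10))
  })
  h <- train_classifier(classifier_spec("rf", list(n_trees = 200L),
                                        seed = 3), ds)
  imp <- feature_importance(h, ds, "permutation", seed = 4, repeats = 5)
  expect_identical(names(which.max(imp)), "V1")
  expect_lt(abs(imp["V10"]), 0.05)   # noise feature ~ no F1 drop
  # deterministic given the seed
  imp2 <- feature_importance(h, ds, "permutation", seed = 4, repeats = 5)
  expect_identical(imp, imp2)
  # impurity route exists for rf only
  imp_g <- feature_importance(h, ds, "impurity")
  expect_identical(names(which.max(imp_g)), "V1")
  hk <- train_classifier(classifier_spec("knn"), ds)
  expect_error(feature_importance(hk, ds, "impurity"), "random forest")
})

test_that("benchmark report is internally consistent", {
  ds <- generate_cohort(cohort_config(seed = 19))
  out <- run_protocol(ds, "leakage_safe",
                      split_spec(0.2, stratified = TRUE, seed = 2),
                      smote_config(seed = 3), enn_config(seed = 4))
  specs <- list(classifier_spec("rf", list(n_trees = 300L), seed = 5),
                classifier_spec("knn", seed = 5))
  rep <- run_benchmark(out$train, out$test, specs,
                       compute_importance = TRUE, importance_repeats = 3)
  expect_identical(nrow(rep$metrics_table), 2L)
  for (m in names(rep$models)) {
    entry <- rep$models[[m]]
    expect_identical(sum(entry$confusion), n_samples(out$test))
    redo <- metrics_from_confusion(entry$confusion)
    row <- rep$metrics_table[rep$metrics_table$model == m, ]
    expect_equal(row$f1, redo$f1)
    expect_equal(row$accuracy, redo$accuracy)
    expect_true(all(unlist(row[-1]) >= 0 & unlist(row[-1]) <= 1))
    # per-model ranks are a permutation of 1..9
    expect_setequal(rank(-entry$importance, ties.method = "first"), 1:9)
  }
  expect_identical(sort(rep$importance$mean_rank$mean_rank),
                   rep$importance$mean_rank$mean_rank)
})
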