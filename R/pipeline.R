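#' Fit a z-score standardizer
#'
#' Records per-feature mean and standard deviation so features can be mapped
#' to z-scores `z = (x - mu) / sigma` and back. The population (divisor `n`)
#' standard deviation is the default; the sample (divisor `n - 1`) form is
#' available via `divisor`.
#'
#' @param ds A validated `hrv_dataset` with at least 2 rows.
#' @param divisor `"n"` (population, default) or `"n-1"` (sample).
#' @return Object of class `standardizer` with fields `mu`, `sigma`,
#'   `feature_names`.
#' @examples
#' ds <- hrv_dataset(cbind(a = c(1, 2, 3)), c(1, 1, 2))
#' s <- fit_standardizer(ds)
#' s$mu     # 2
#' s$sigma  # sqrt(2/3)
#' @export
fit_standardizer <- function(ds, divisor = c("n", "n-1")) {
  validate_hrv_dataset(ds)
  divisor <- match.arg(divisor)
  n <- n_samples(ds)
  if (n < 2) stop("need at least 2 rows to fit a standardizer")
  mu <- colMeans(ds$features)
  ss <- colSums(sweep(ds$features, 2, mu)^2)
  sigma <- sqrt(ss / if (divisor == "n") n else n - 1)
  zero <- which(sigma <= 0)
  if (length(zero))
    stop("constant feature cannot be standardized: '",
         ds$feature_names[zero[1]], "'")
  structure(list(mu = mu, sigma = sigma, feature_names = ds$feature_names),
            class = "standardizer")
}

#' @export
print.standardizer <- function(x, ...) {
  cat("<standardizer> ", length(x$mu), " features\n", sep = "")
  print(data.frame(feature = x$feature_names, mu = x$mu, sigma = x$sigma,
                   row.names = NULL))
  invisible(x)
}

#' Apply / invert a standardizer
#'
#' `apply_standardizer()` maps features to z-scores; on the data the
#' standardizer was fitted to, every column then has mean 0 and population
#' standard deviation 1. `invert_standardizer()` is its exact inverse.
#'
#' @param ds A validated `hrv_dataset`.
#' @param s A fitted `standardizer` with matching feature count.
#' @return A new `hrv_dataset` with transformed features.
#' @export
apply_standardizer <- function(ds, s) {
  check_standardizer(ds, s)
  z <- sweep(sweep(ds$features, 2, s$mu), 2, s$sigma, "/")
  hrv_dataset(z, ds$labels, ds$feature_names, ds$provenance, ds$label_set)
}

#' @rdname apply_standardizer
#' @export
invert_standardizer <- function(ds, s) {
  check_standardizer(ds, s)
  x <- sweep(sweep(ds$features, 2, s$sigma, "*"), 2, s$mu, "+")
  hrv_dataset(x, ds$labels, ds$feature_names, ds$provenance, ds$label_set)
}

check_standardizer <- function(ds, s) {
  stopifnot(inherits(s, "standardizer"))
  if (ncol(ds$features) != length(s$mu))
    stop("feature count mismatch: dataset has ", ncol(ds$features),
         ", standardizer has ", length(s$mu))
  invisible(TRUE)
}

#' Refined SMOTE-ENN resampling
#'
#' The full optimisation pipeline: fit a z-score standardizer, oversample
#' minority classes by refined SMOTE in standardized space, clean the
#' augmented data with refined ENN, and invert the standardization so the
#' output is in the original units. Per-class bookkeeping records original,
#' synthetic-added, removed and final counts, and the identity
#' `final = original + synthetic - removed` holds per class.
#'
#' @param ds A validated `hrv_dataset` with at least 2 classes.
#' @param smote_cfg A [smote_config()].
#' @param enn_cfg An [enn_config()].
#' @param standardize_divisor Passed to [fit_standardizer()].
#' @return Object of class `resample_result`: fields `dataset` (the
#'   optimised `hrv_dataset`), `per_class_counts` (data.frame), `mode`
#'   (filled by [run_protocol()], `NA` here), `smote_cfg`, `enn_cfg`,
#'   `standardizer`.
#' @export
refined_smote_enn <- function(ds, smote_cfg = smote_config(),
                              enn_cfg = enn_config(),
                              standardize_divisor = "n") {
  validate_hrv_dataset(ds)
  if (length(unique(ds$labels)) < 2)
    stop("resampling needs at least 2 distinct classes")
  s <- fit_standardizer(ds, divisor = standardize_divisor)
  z <- apply_standardizer(ds, s)
  aug <- generate_synthetic(z, smote_cfg)
  edited <- edit_with_retention(aug, enn_cfg)
  out <- invert_standardizer(edited$dataset, s)

  orig <- table(factor(ds$labels, levels = ds$label_set))
  augc <- table(factor(aug$labels, levels = aug$label_set))
  fin <- table(factor(out$labels, levels = out$label_set))
  counts <- data.frame(
    class = ds$label_set,
    original = as.integer(orig),
    synthetic_added = as.integer(augc) - as.integer(orig),
    removed = as.integer(augc) - as.integer(fin),
    final = as.integer(fin))
  stopifnot(all(counts$final ==
                  counts$original + counts$synthetic_added - counts$removed),
            sum(counts$final) == n_samples(out))
  structure(list(dataset = out, per_class_counts = counts, mode = NA_character_,
                 smote_cfg = smote_cfg, enn_cfg = enn_cfg,
                 enn_report = edited$report, standardizer = s),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat("<resample_result>",
      if (!is.na(x$mode)) paste0(" mode = ", x$mode), "\n", sep = "")
  print(x$per_class_counts, row.names = FALSE)
  cat("total:", sum(x$per_class_counts$original), "->",
      sum(x$per_class_counts$final), "samples\n")
  invisible(x)
}

#' Run the resampling protocol around a train/test split
#'
#' Two orderings of resampling and splitting are supported. In
#' `paper_faithful` mode the whole dataset is resampled and then split, so
#' synthetic rows derived from test-set originals can enter the training
#' set (the optimistic protocol some studies use). In `leakage_safe` mode
#' (recommended) the split happens first and only the training partition is
#' resampled; the test partition stays untouched and all-original.
#'
#' @param ds A validated `hrv_dataset`.
#' @param mode `"leakage_safe"` (default) or `"paper_faithful"`.
#' @param split A [split_spec()].
#' @param smote_cfg A [smote_config()].
#' @param enn_cfg An [enn_config()].
#' @return List with `train`, `test` (both `hrv_dataset`) and `result`
#'   (the `resample_result`, with `mode` filled in).
#' @export
run_protocol <- function(ds, mode = c("leakage_safe", "paper_faithful"),
                         split = split_spec(), smote_cfg = smote_config(),
                         enn_cfg = enn_config()) {
  mode <- match.arg(mode)
  if (mode == "paper_faithful") {
    res <- refined_smote_enn(ds, smote_cfg, enn_cfg)
    parts <- split_train_test(res$dataset, split)
  } else {
    parts0 <- split_train_test(ds, split)
    res <- refined_smote_enn(parts0$train, smote_cfg, enn_cfg)
    parts <- list(train = res$dataset, test = parts0$test)
  }
  res$mode <- mode
  list(train = parts$train, test = parts$test, result = res)
}
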