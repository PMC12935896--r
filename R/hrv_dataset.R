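#' ANS state labels
#'
#' The seven autonomic-nervous-system (ANS) state labels used for HRV
#' classification, as an integer-to-name map. Label columns in CSV files may
#' use either the integer codes or these exact names.
#'
#' @return Named character vector; names are the integer codes "1".."7".
#' @export
ans_state_names <- function() {
  c(`1` = "Fatigue",
    `2` = "Sympathetic nervous system disorder",
    `3` = "Autonomic nervous system excitability",
    `4` = "Autonomic nervous system balance",
    `5` = "Dysautonomia",
    `6` = "Stress",
    `7` = "Vagus nerve disorder")
}

#' Default HRV feature names
#'
#' The nine time- and frequency-domain HRV features the method operates on:
#' heart rate, SDNN, rmSSD, pNN50, spectral powers (VLF/LF/HF), total
#' spectral power and the LF/HF ratio.
#'
#' @return Character vector of length 9.
#' @export
hrv_feature_names <- function() {
  c("HR", "SDNN", "rmSSD", "PNN50", "VLF", "LF", "HF", "TSP", "LF.HF")
}

.provenance_levels <- c("original", "synthetic_inline", "synthetic_offline")

#' Construct an HRV dataset
#'
#' Typed container for a numeric feature matrix with integer class labels and
#' per-row provenance (whether a row is an original observation or was
#' synthesised by in-line / off-line interpolation).
#'
#' @param features Numeric matrix (rows = samples) or data.frame of numeric
#'   columns.
#' @param labels Integer class label per row, drawn from `label_set`.
#' @param feature_names Column names; defaults to existing colnames, else
#'   [hrv_feature_names()] when the width is 9, else `V1..Vp`.
#' @param provenance Per-row tag in `original`, `synthetic_inline`,
#'   `synthetic_offline`. Defaults to all `original`.
#' @param label_set Admissible label values; defaults to the sorted unique
#'   labels present.
#' @return Object of class `hrv_dataset` with fields `features`, `labels`,
#'   `feature_names`, `provenance`, `label_set`.
#' @examples
#' ds <- hrv_dataset(matrix(rnorm(20), 10, 2), rep(1:2, each = 5))
#' n_samples(ds)
#' @export
hrv_dataset <- function(features, labels, feature_names = NULL,
                        provenance = NULL, label_set = NULL) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features)) features <- matrix(features, nrow = length(labels))
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) {
      feature_names <- if (ncol(features) == 9L) hrv_feature_names()
                       else paste0("V", seq_len(ncol(features)))
    }
  }
  if (length(feature_names) == ncol(features))
    colnames(features) <- feature_names
  if (is.null(provenance)) provenance <- rep("original", nrow(features))
  if (is.null(label_set)) label_set <- sort(unique(labels))
  ds <- structure(
    list(features = features, labels = labels,
         feature_names = feature_names, provenance = provenance,
         label_set = as.integer(label_set)),
    class = "hrv_dataset")
  validate_hrv_dataset(ds)
}

#' Validate an HRV dataset
#'
#' Checks the container invariants: consistent lengths, finite feature
#' values, and labels within the declared label set.
#'
#' @param ds An `hrv_dataset`.
#' @return `ds`, invisibly unchanged, or an error describing the violation.
#' @export
validate_hrv_dataset <- function(ds) {
  stopifnot(inherits(ds, "hrv_dataset"))
  n <- nrow(ds$features)
  if (length(ds$labels) != n)
    stop("labels length (", length(ds$labels), ") != feature rows (", n, ")")
  if (length(ds$provenance) != n)
    stop("provenance length (", length(ds$provenance), ") != feature rows (", n, ")")
  if (length(ds$feature_names) != ncol(ds$features))
    stop("feature_names length != feature columns")
  bad_prov <- setdiff(unique(ds$provenance), .provenance_levels)
  if (length(bad_prov))
    stop("invalid provenance value(s): ", paste(bad_prov, collapse = ", "))
  if (n > 0) {
    nf <- which(!is.finite(ds$features), arr.ind = TRUE)
    if (nrow(nf))
      stop("non-finite feature value at row ", nf[1, 1], ", column '",
           ds$feature_names[nf[1, 2]], "'")
    bad <- setdiff(unique(ds$labels), ds$label_set)
    if (length(bad))
      stop("label(s) outside declared label set: ", paste(bad, collapse = ", "))
  }
  ds
}

#' @export
print.hrv_dataset <- function(x, ...) {
  cat("<hrv_dataset> ", nrow(x$features), " samples x ",
      ncol(x$features), " features\n", sep = "")
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  tab <- table(factor(x$labels, levels = x$label_set))
  cat("  class counts:",
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " "), "\n")
  ptab <- table(x$provenance)
  cat("  provenance:",
      paste(sprintf("%s:%d", names(ptab), as.integer(ptab)), collapse = " "), "\n")
  invisible(x)
}

#' Number of samples in a dataset
#' @param ds An `hrv_dataset`.
#' @return Integer row count.
#' @export
n_samples <- function(ds) nrow(ds$features)

#' Subset an HRV dataset by row indices
#' @param ds An `hrv_dataset`.
#' @param idx Integer row indices (or logical mask).
#' @return A new `hrv_dataset` with the selected rows, same label set.
#' @export
subset_rows <- function(ds, idx) {
  hrv_dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
              feature_names = ds$feature_names,
              provenance = ds$provenance[idx], label_set = ds$label_set)
}

#' Append rows to an HRV dataset
#' @param ds An `hrv_dataset`.
#' @param features Numeric matrix of new rows (same width).
#' @param labels Integer labels for the new rows.
#' @param provenance Provenance tags for the new rows.
#' @return A new `hrv_dataset`.
#' @export
bind_rows_hrv <- function(ds, features, labels, provenance) {
  hrv_dataset(rbind(ds$features, features), c(ds$labels, as.integer(labels)),
              feature_names = ds$feature_names,
              provenance = c(ds$provenance, provenance),
              label_set = ds$label_set)
}

#' Read an HRV dataset from CSV
#'
#' Reads a comma-separated file with a header row: numeric feature columns
#' plus one label column. The label column may hold integer codes or the
#' exact ANS state names of [ans_state_names()]. A `provenance` column, if
#' present, is used; otherwise all rows are tagged `original`.
#'
#' @param path CSV file path.
#' @param label_column Name of the label column (default `"label"`).
#' @param label_set Admissible labels; default deduced from the data (1:7 if
#'   state names were used).
#' @return A validated `hrv_dataset`; feature column order is preserved.
#' @export
read_dataset <- function(path, label_column = "label", label_set = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) stop("empty file: ", path)
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found in ", path)
  lab_raw <- df[[label_column]]
  if (is.character(lab_raw)) {
    nm <- ans_state_names()
    mapped <- match(lab_raw, nm)
    int_ok <- suppressWarnings(as.integer(lab_raw))
    labels <- ifelse(!is.na(mapped), mapped, int_ok)
    if (anyNA(labels) && nrow(df) > 0)
      stop("unrecognised label value '", lab_raw[which(is.na(labels))[1]],
           "' at row ", which(is.na(labels))[1])
    if (is.null(label_set) && any(!is.na(mapped))) label_set <- 1:7
  } else labels <- as.integer(lab_raw)
  prov <- NULL
  if ("provenance" %in% names(df)) {
    prov <- as.character(df[["provenance"]])
    df[["provenance"]] <- NULL
  }
  df[[label_column]] <- NULL
  for (cn in names(df)) {
    v <- df[[cn]]
    if (is.character(v) || is.logical(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) | !nzchar(trimws(as.character(v))))
      if (length(bad))
        stop("non-numeric or blank value in column '", cn, "' at data row ", bad[1])
      df[[cn]] <- conv
    }
    if (anyNA(df[[cn]]))
      stop("missing value in column '", cn, "' at data row ",
           which(is.na(df[[cn]]))[1])
  }
  hrv_dataset(as.matrix(df), labels, feature_names = names(df),
              provenance = prov, label_set = label_set)
}

#' Write an HRV dataset to CSV
#'
#' Serialises features, labels and (optionally) provenance with enough
#' significant digits (17) that a write/read round-trip reproduces the
#' feature matrix bit-for-bit.
#'
#' @param ds A validated `hrv_dataset`.
#' @param path Output file path.
#' @param label_column Label column name (default `"label"`).
#' @param include_provenance Add a `provenance` column (default `FALSE`).
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(ds, path, label_column = "label",
                          include_provenance = FALSE) {
  validate_hrv_dataset(ds)
  df <- as.data.frame(apply(ds$features, 2, function(x) sprintf("%.17g", x)))
  if (n_samples(ds) == 0)
    df <- as.data.frame(matrix(character(0), 0, ncol(ds$features)))
  names(df) <- ds$feature_names
  df[[label_column]] <- ds$labels
  if (include_provenance) df[["provenance"]] <- ds$provenance
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Train/test split specification
#'
#' @param test_fraction Fraction of rows in the test partition, in (0,1);
#'   default 0.2.
#' @param stratified Stratify the draw by class so per-class test counts track
#'   `n_c * test_fraction` (default `FALSE`: simple random draw).
#' @param seed Integer seed controlling the draw.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.2, stratified = FALSE, seed = 1L) {
  stopifnot(is.numeric(test_fraction), test_fraction > 0, test_fraction < 1)
  structure(list(test_fraction = test_fraction, stratified = isTRUE(stratified),
                 seed = as.integer(seed)), class = "split_spec")
}

#' Split a dataset into train and test partitions
#'
#' The test partition holds `ceiling(n * test_fraction)` rows (so a 1172-row
#' dataset at 20% yields the conventional 937/235 partition); with
#' stratification, per-class test counts are apportioned by largest remainder
#' so each differs from `n_c * test_fraction` by less than 1. The same seed
#' always reproduces the same split.
#'
#' @param ds A validated `hrv_dataset`.
#' @param spec A [split_spec()].
#' @return List with elements `train` and `test` (both `hrv_dataset`).
#' @export
split_train_test <- function(ds, spec = split_spec()) {
  validate_hrv_dataset(ds)
  stopifnot(inherits(spec, "split_spec"))
  n <- n_samples(ds)
  n_test <- ceiling(n * spec$test_fraction)
  if (n_test < 1 || n_test >= n)
    stop("test_fraction leaves an empty partition (n = ", n, ")")
  test_idx <- with_seed(spec$seed, {
    if (!spec$stratified) {
      sort(sample.int(n, n_test))
    } else {
      cls <- ds$labels
      tab <- table(cls)
      if (any(tab < 2))
        stop("stratified split needs >= 2 members per class; class ",
             names(tab)[which(tab < 2)[1]], " has ", min(tab))
      quota <- largest_remainder(as.numeric(tab) * spec$test_fraction, n_test)
      idx <- integer(0)
      for (i in seq_along(tab)) {
        members <- which(cls == as.integer(names(tab)[i]))
        if (quota[i] > 0)
          idx <- c(idx, members[sample.int(length(members), quota[i])])
      }
      sort(idx)
    }
  })
  list(train = subset_rows(ds, setdiff(seq_len(n), test_idx)),
       test = subset_rows(ds, test_idx))
}
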