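#' Confusion matrix over a fixed label set
#'
#' @param y_true,y_pred Integer label vectors of equal length.
#' @param label_set Row/column order; defaults to the sorted union of the
#'   observed labels.
#' @return Integer matrix; entry `(i, j)` counts true class `i` predicted as
#'   class `j`. Entries sum to `length(y_true)`.
#' @export
confusion_matrix <- function(y_true, y_pred, label_set = NULL) {
  if (length(y_true) != length(y_pred))
    stop("length mismatch: ", length(y_true), " vs ", length(y_pred))
  if (is.null(label_set)) label_set <- sort(unique(c(y_true, y_pred)))
  unk <- setdiff(unique(c(y_true, y_pred)), label_set)
  if (length(unk)) stop("label(s) outside label set: ", paste(unk, collapse = ", "))
  f <- function(v) factor(v, levels = label_set)
  cm <- table(true = f(y_true), predicted = f(y_pred))
  matrix(as.integer(cm), nrow = length(label_set),
         dimnames = list(true = as.character(label_set),
                         predicted = as.character(label_set)))
}

#' Accuracy and macro metrics from a confusion matrix
#'
#' Per-class one-vs-rest precision, recall and F1 are averaged with equal
#' class weight (macro averaging); micro averaging (pooled counts, which for
#' single-label classification equals accuracy) is available via `average`.
#' A class never predicted gets precision 0 and is reported in
#' `zero_prediction_classes`; a class with no true members gets recall 0.
#'
#' @param cm Square nonnegative count matrix (rows = true classes).
#' @param average `"macro"` (default) or `"micro"`.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, the per-class
#'   vectors `per_class`, and `zero_prediction_classes`.
#' @export
metrics_from_confusion <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (sum(cm) == 0) stop("confusion matrix is all zero")
  if (is.null(rownames(cm))) rownames(cm) <- seq_len(nrow(cm))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  acc <- sum(tp) / sum(cm)
  if (average == "macro") {
    out <- list(accuracy = acc, precision = mean(prec), recall = mean(rec),
                f1 = mean(f1))
  } else {
    mp <- sum(tp) / (sum(tp) + sum(fp))
    mr <- sum(tp) / (sum(tp) + sum(fn))
    out <- list(accuracy = acc, precision = mp, recall = mr,
                f1 = 2 * mp * mr / (mp + mr))
  }
  out$per_class <- data.frame(class = rownames(cm), precision = prec,
                              recall = rec, f1 = f1, row.names = NULL)
  out$zero_prediction_classes <- rownames(cm)[tp + fp == 0]
  out
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, treats that class as positive and its score column as the
#' discriminant, building the ROC curve and AUC (trapezoidal /
#' Mann-Whitney-equivalent, midpoint tie handling) via \pkg{pROC}. Classes
#' absent from `y_true` have undefined AUC and are excluded from the macro
#' mean with a warning.
#'
#' @param y_true Integer label vector.
#' @param scores Numeric matrix, one column per class (named by label);
#'   higher score means more likely that class.
#' @param label_set Class order; defaults to `colnames(scores)`.
#' @return List with `auc` (named per-class vector, `NA` where undefined),
#'   `macro_auc`, and `curves` (per-class data.frames of `fpr`, `tpr`).
#' @export
roc_auc_ovr <- function(y_true, scores, label_set = NULL) {
  scores <- as.matrix(scores)
  if (is.null(label_set)) label_set <- colnames(scores)
  if (is.null(label_set)) stop("label_set or score column names required")
  if (length(label_set) != ncol(scores))
    stop("one score column per class required")
  aucs <- stats::setNames(rep(NA_real_, length(label_set)),
                          as.character(label_set))
  curves <- stats::setNames(vector("list", length(label_set)),
                            as.character(label_set))
  for (i in seq_along(label_set)) {
    cls <- label_set[i]
    pos <- as.integer(y_true == cls)
    if (length(unique(pos)) < 2) next
    r <- pROC::roc(response = pos, predictor = scores[, i], quiet = TRUE,
                   direction = "<", levels = c(0, 1))
    aucs[i] <- as.numeric(pROC::auc(r))
    curves[[i]] <- data.frame(fpr = 1 - r$specificities,
                              tpr = r$sensitivities)
  }
  if (anyNA(aucs))
    warning("class(es) absent from y_true excluded from macro AUC: ",
            paste(names(aucs)[is.na(aucs)], collapse = ", "))
  list(auc = aucs, macro_auc = mean(aucs, na.rm = TRUE), curves = curves)
}

#' Per-model feature ranks and cross-model mean ranks
#'
#' Within each model, the feature with the largest importance score gets
#' rank 1 (ties share the average rank); the mean rank of a feature is the
#' arithmetic mean of its ranks across models.
#'
#' @param scores_by_model Named list: model name -> named numeric vector of
#'   per-feature importance scores (all models over the same features).
#' @return List with `ranks` (matrix, models x features) and `mean_rank`
#'   (data.frame sorted ascending by mean rank).
#' @export
rank_and_mean_rank <- function(scores_by_model) {
  stopifnot(length(scores_by_model) >= 1)
  feats <- names(scores_by_model[[1]])
  for (m in names(scores_by_model))
    if (!setequal(names(scores_by_model[[m]]), feats))
      stop("model '", m, "' covers a different feature set")
  ranks <- t(vapply(scores_by_model,
                    function(s) rank(-s[feats], ties.method = "average"),
                    numeric(length(feats))))
  colnames(ranks) <- feats
  mr <- colMeans(ranks)
  list(ranks = ranks,
       mean_rank = data.frame(feature = feats, mean_rank = mr,
                              row.names = NULL)[order(mr), ])
}
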