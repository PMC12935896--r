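#' Refined-ENN configuration
#'
#' Knobs of the refined Edited Nearest Neighbor cleaner: samples whose label
#' disagrees with their k-NN vote are treated as boundary/noise, and all but
#' a retained fraction of them are removed.
#'
#' @param k_neighbors Neighbourhood size for the consistency vote (default 3).
#' @param retain_fraction Fraction of flagged boundary rows to keep, in
#'   \[0, 1\]; the default 0.15 sits in the 10--20% band the method
#'   prescribes.
#' @param stratified_retention Draw the retained rows per class (largest
#'   remainder apportionment) so tiny classes are not wiped (default `TRUE`).
#' @param seed Integer seed for the retention draw.
#' @return Object of class `enn_config`.
#' @export
enn_config <- function(k_neighbors = 3L, retain_fraction = 0.15,
                       stratified_retention = TRUE, seed = 1L) {
  stopifnot(k_neighbors >= 1, retain_fraction >= 0, retain_fraction <= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 retain_fraction = retain_fraction,
                 stratified_retention = isTRUE(stratified_retention),
                 seed = as.integer(seed)),
            class = "enn_config")
}

#' k-NN consistency vote for one row
#'
#' Finds the `k` nearest rows to `index` (any class, excluding the row
#' itself; distance ties broken by lower row index) and returns the unique
#' plurality label among them, or `NA` when the vote is tied (the row is
#' then treated as lying on the decision boundary).
#'
#' @param ds A validated `hrv_dataset` with at least `k + 1` rows.
#' @param index Query row index.
#' @param k Neighbourhood size.
#' @return Integer label, or `NA_integer_` for a tied (boundary) vote.
#' @export
classify_by_neighbors <- function(ds, index, k) {
  n <- n_samples(ds)
  if (n < k + 1) stop("dataset has ", n, " rows; need at least ", k + 1)
  others <- setdiff(seq_len(n), index)
  d <- sqrt(colSums((t(ds$features[others, , drop = FALSE]) -
                       ds$features[index, ])^2))
  nb <- others[order(d, others)[seq_len(k)]]
  vote_label(ds$labels[nb])
}

# Unique plurality of a label vector; NA on ties.
vote_label <- function(labs) {
  tab <- table(labs)
  top <- which(tab == max(tab))
  if (length(top) != 1) return(NA_integer_)
  as.integer(names(tab)[top])
}

#' Flag boundary rows by k-NN label consistency
#'
#' A row is flagged when the k-NN vote ([classify_by_neighbors()]) disagrees
#' with its own label; a tied vote counts as disagreement. All flags are
#' computed simultaneously from the input dataset — no sequential deletion.
#'
#' @param ds A validated `hrv_dataset`.
#' @param k Neighbourhood size (default 3).
#' @return Logical mask over rows; `TRUE` marks a boundary/noise row.
#' @export
flag_boundary <- function(ds, k = 3L) {
  validate_hrv_dataset(ds)
  n <- n_samples(ds)
  if (n < k + 1) stop("dataset has ", n, " rows; need at least ", k + 1)
  dm <- pairwise_distances(ds$features)
  diag(dm) <- Inf
  vapply(seq_len(n), function(i) {
    nb <- order(dm[i, ], seq_len(n))[seq_len(k)]
    v <- vote_label(ds$labels[nb])
    is.na(v) || v != ds$labels[i]
  }, logical(1))
}

#' Edit a dataset with partial boundary retention (refined ENN)
#'
#' Removes the boundary rows flagged by [flag_boundary()], except for a
#' retained subset: `round(retain_fraction * n_flagged)` rows drawn
#' uniformly at random (per class, largest-remainder apportionment, when
#' `stratified_retention`). Removal never empties a class: if every member
#' of a class is flagged and none was retained, the flagged member nearest
#' the class centroid is kept back with a warning.
#'
#' @param ds A validated `hrv_dataset`.
#' @param cfg An [enn_config()].
#' @return List with `dataset` (the edited `hrv_dataset`) and `report`, a
#'   data.frame with per-class columns `class`, `n_input`, `kept_consistent`,
#'   `retained_boundary`, `removed`, `n_output`.
#' @export
edit_with_retention <- function(ds, cfg = enn_config()) {
  validate_hrv_dataset(ds)
  stopifnot(inherits(cfg, "enn_config"))
  mask <- flag_boundary(ds, cfg$k_neighbors)
  flagged <- which(mask)
  n_retain <- round(cfg$retain_fraction * length(flagged))
  retained <- integer(0)
  if (n_retain > 0 && length(flagged) > 0) {
    retained <- with_seed(cfg$seed, {
      if (!cfg$stratified_retention) {
        flagged[sample.int(length(flagged), n_retain)]
      } else {
        fl_cls <- ds$labels[flagged]
        tab <- table(fl_cls)
        quota <- largest_remainder(
          as.numeric(tab) / length(flagged) * n_retain, n_retain)
        quota <- pmin(quota, as.integer(tab))
        out <- integer(0)
        for (i in seq_along(tab)) {
          members <- flagged[fl_cls == as.integer(names(tab)[i])]
          if (quota[i] > 0)
            out <- c(out, members[sample.int(length(members), quota[i])])
        }
        out
      }
    })
  }
  # empty-class rescue: keep back the flagged row nearest its class centroid
  for (cls in ds$label_set) {
    members <- which(ds$labels == cls)
    if (!length(members)) next
    surviving <- setdiff(members, setdiff(flagged, retained))
    if (!length(surviving)) {
      cand <- intersect(flagged, members)
      centroid <- colMeans(ds$features[members, , drop = FALSE])
      dc <- sqrt(colSums((t(ds$features[cand, , drop = FALSE]) - centroid)^2))
      rescue <- cand[which.min(dc)]
      retained <- c(retained, rescue)
      warning("class ", cls, " would be emptied; retained its ",
              "nearest-to-centroid boundary row (", rescue, ")")
    }
  }
  keep <- sort(c(setdiff(seq_len(n_samples(ds)), flagged), retained))
  out <- subset_rows(ds, keep)
  report <- per_class_edit_report(ds, flagged, retained)
  list(dataset = out, report = report)
}

per_class_edit_report <- function(ds, flagged, retained) {
  cls_levels <- ds$label_set
  do.call(rbind, lapply(cls_levels, function(cls) {
    members <- which(ds$labels == cls)
    fl <- intersect(flagged, members)
    rt <- intersect(retained, members)
    data.frame(class = cls,
               n_input = length(members),
               kept_consistent = length(members) - length(fl),
               retained_boundary = length(rt),
               removed = length(fl) - length(rt),
               n_output = length(members) - length(fl) + length(rt))
  }))
}
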