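# Small in-code fixtures shared across the suite.

# Random dataset: n rows, p features, labels drawn from `classes`.
random_dataset <- function(n, p = 9, classes = 1:2, seed = 1) {
  rsmoteenn:::with_seed(seed, {
    hrv_dataset(matrix(rnorm(n * p), n, p),
                sample(classes, n, replace = TRUE),
                feature_names = paste0("V", seq_len(p)))
  })
}

# Two tight, well-separated clusters (classes 1 and 2), p-dimensional.
# The centre offset is spread over every dimension so the separation
# survives per-column standardization.
two_cluster_dataset <- function(n_per_class = 10, p = 9, separation = 50,
                                seed = 1) {
  rsmoteenn:::with_seed(seed, {
    x1 <- matrix(rnorm(n_per_class * p, sd = 0.5), n_per_class, p)
    x2 <- matrix(rnorm(n_per_class * p, sd = 0.5), n_per_class, p)
    x2 <- x2 + separation / sqrt(p)
    hrv_dataset(rbind(x1, x2), rep(1:2, each = n_per_class),
                feature_names = paste0("V", seq_len(p)))
  })
}

# Brute-force k-NN majority-vote oracle for ENN flagging: all-pairs
# distances, ties by lower index, unique plurality else boundary.
oracle_flag_boundary <- function(ds, k) {
  n <- n_samples(ds)
  sapply(seq_len(n), function(i) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- euclidean_distance(ds$features[i, ],
                                                     ds$features[j, ])
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    tab <- table(ds$labels[nb])
    top <- names(tab)[tab == max(tab)]
    if (length(top) != 1) return(TRUE)
    as.integer(top) != ds$labels[i]
  })
}

# Mann-Whitney rank-statistic AUC oracle.
oracle_auc <- function(pos_scores, neg_scores) {
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  n1 <- length(pos_scores); n2 <- length(neg_scores)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Tiny imbalanced cohort used by pipeline tests: class counts {6, 195}.
imbalanced_pair_cohort <- function(seed = 2) {
  prof <- default_profiles(counts = c(0L, 6L, 0L, 195L, 0L, 0L, 0L))
  generate_cohort(cohort_config(profiles = prof[c(2, 4)], seed = seed))
}
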