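#' Default class profiles for the synthetic HRV cohort
#'
#' Seven class-conditional profiles over the seven base HRV features (HR,
#' SDNN, rmSSD, PNN50, VLF, LF, HF). Features are modelled log-normally —
#' spectral powers are positive and right-skewed — so each profile carries a
#' log-space location vector, a log-space scale vector and a shared
#' inter-feature correlation matrix. Locations encode the ANS physiology of
#' each state directionally: e.g. Stress has high HR and LF with depressed
#' SDNN/rmSSD/HF (sympathetic excitation), Fatigue elevated rmSSD/HF with
#' lowered LF (parasympathetic rebound), Balance sits mid-range. Default
#' class counts are the imbalanced cohort sizes \{63, 6, 9, 195, 12, 24, 12\}.
#'
#' @param counts Integer vector of 7 per-class sample counts.
#' @param overlap Nonnegative scalar shrinking between-class separation;
#'   class location offsets are scaled by `1 / (1 + overlap)`. Default 0.5.
#' @return List of 7 `class_profile` lists with fields `label`, `count`,
#'   `mu_log`, `sigma_log`, `corr`.
#' @export
default_profiles <- function(counts = c(63L, 6L, 9L, 195L, 12L, 24L, 12L),
                             overlap = 0.5) {
  stopifnot(length(counts) == 7, all(counts >= 0), overlap >= 0)
  base_feats <- c("HR", "SDNN", "rmSSD", "PNN50", "VLF", "LF", "HF")
  # log-space baselines: HR ~70 bpm, SDNN ~50 ms, rmSSD ~35 ms, PNN50 ~12 %,
  # VLF ~1000 / LF ~700 / HF ~500 ms^2
  mu0 <- c(HR = log(70), SDNN = log(50), rmSSD = log(35), PNN50 = log(12),
           VLF = log(1000), LF = log(700), HF = log(500))
  sd0 <- c(HR = 0.08, SDNN = 0.25, rmSSD = 0.30, PNN50 = 0.50,
           VLF = 0.40, LF = 0.40, HF = 0.45)
  # class offsets in within-class-sd units, one row per ANS state
  shift <- rbind(
    Fatigue      = c(-0.8,  0.3,  1.2,  1.0,  0.0, -0.6,  1.2),
    SympDisorder = c(-0.4, -1.0,  0.5,  0.3, -0.5, -1.8,  0.6),
    Excitability = c( 0.6,  1.5,  1.0,  0.8,  1.2,  1.5,  1.5),
    Balance      = c( 0.0,  0.0,  0.0,  0.0,  0.0,  0.0,  0.0),
    Dysautonomia = c( 0.3, -1.5, -1.2, -1.2, -1.2, -1.0, -1.2),
    Stress       = c( 1.5, -1.2, -1.5, -1.5,  0.3,  1.0, -1.5),
    Vagus        = c( 0.5, -0.5, -1.8, -1.8,  0.0,  0.2, -2.0))
  colnames(shift) <- base_feats
  corr <- hrv_base_correlation()
  # base multiplier 2.5 puts the default cohort (overlap = 0.5) in the
  # regime the generator is meant to emulate: majority classes classify
  # well untreated while minority classes visibly underperform
  sep <- 2.5 / (1 + overlap)
  lapply(1:7, function(i) {
    structure(list(label = i, count = as.integer(counts[i]),
                   mu_log = mu0 + sep * shift[i, ] * sd0,
                   sigma_log = sd0, corr = corr),
              class = "class_profile")
  })
}

# Correlation structure among the 7 base features in log space: the
# vagally-mediated trio SDNN/rmSSD/PNN50 co-varies strongly, rmSSD couples
# to HF, spectral bands co-vary mildly, HR runs weakly against variability.
hrv_base_correlation <- function() {
  f <- c("HR", "SDNN", "rmSSD", "PNN50", "VLF", "LF", "HF")
  R <- diag(7); dimnames(R) <- list(f, f)
  set_r <- function(a, b, v) { R[a, b] <<- v; R[b, a] <<- v }
  set_r("HR", "SDNN", -0.30); set_r("HR", "rmSSD", -0.30)
  set_r("HR", "PNN50", -0.20); set_r("HR", "VLF", -0.10)
  set_r("HR", "LF", -0.10); set_r("HR", "HF", -0.20)
  set_r("SDNN", "rmSSD", 0.70); set_r("SDNN", "PNN50", 0.50)
  set_r("SDNN", "VLF", 0.40); set_r("SDNN", "LF", 0.40)
  set_r("SDNN", "HF", 0.40)
  set_r("rmSSD", "PNN50", 0.70); set_r("rmSSD", "VLF", 0.20)
  set_r("rmSSD", "LF", 0.20); set_r("rmSSD", "HF", 0.60)
  set_r("PNN50", "VLF", 0.10); set_r("PNN50", "LF", 0.10)
  set_r("PNN50", "HF", 0.50)
  set_r("VLF", "LF", 0.30); set_r("VLF", "HF", 0.20)
  set_r("LF", "HF", 0.30)
  R
}

#' Synthetic cohort configuration
#'
#' @param profiles List of class profiles (default [default_profiles()]).
#' @param noise_sd Standard deviation of the multiplicative residual on the
#'   spectral-sum identity `TSP = (VLF + LF + HF) * (1 + eps)`; default 0.02.
#' @param seed Integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(profiles = default_profiles(), noise_sd = 0.02,
                          seed = 1L) {
  stopifnot(length(profiles) >= 2, noise_sd >= 0)
  structure(list(profiles = profiles, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "cohort_config")
}

#' Generate a synthetic imbalanced HRV cohort
#'
#' Per class, draws correlated multivariate-normal vectors in log space and
#' exponentiates them, so the seven base features are positive and
#' right-skewed. The two derived features are then constructed to carry the
#' known couplings of real HRV panels: `TSP = (VLF + LF + HF) * (1 + eps)`
#' with `eps ~ N(0, noise_sd)`, and `LF/HF` as the exact ratio. Columns
#' follow [hrv_feature_names()] order; class counts match the profiles
#' exactly and the same seed reproduces the cohort.
#'
#' @param cfg A [cohort_config()].
#' @return A validated `hrv_dataset` with label set 1..7.
#' @examples
#' ds <- generate_cohort(cohort_config(seed = 7))
#' table(ds$labels)
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    blocks <- lapply(cfg$profiles, function(p) {
      if (p$count == 0) return(NULL)
      ev <- eigen(p$corr, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 1e-10)
        stop("correlation matrix for class ", p$label, " is not positive definite")
      Sigma <- diag(p$sigma_log) %*% p$corr %*% diag(p$sigma_log)
      logx <- MASS::mvrnorm(p$count, mu = p$mu_log, Sigma = Sigma)
      if (p$count == 1) logx <- matrix(logx, nrow = 1)
      base <- exp(logx)
      colnames(base) <- names(p$mu_log)
      eps <- if (cfg$noise_sd > 0) stats::rnorm(p$count, 0, cfg$noise_sd)
             else rep(0, p$count)
      tsp <- (base[, "VLF"] + base[, "LF"] + base[, "HF"]) * (1 + eps)
      lfhf <- base[, "LF"] / base[, "HF"]
      list(features = cbind(base[, c("HR", "SDNN", "rmSSD", "PNN50",
                                     "VLF", "LF", "HF")],
                            TSP = tsp, LF.HF = lfhf),
           labels = rep(p$label, p$count))
    })
    blocks <- Filter(Negate(is.null), blocks)
    hrv_dataset(do.call(rbind, lapply(blocks, `[[`, "features")),
                unlist(lapply(blocks, `[[`, "labels")),
                feature_names = hrv_feature_names(),
                label_set = vapply(cfg$profiles, `[[`, integer(1), "label"))
  })
}

#' Two-cluster cohort with planted boundary points
#'
#' Fixture for edited-nearest-neighbour evaluation: two well-separated
#' 9-dimensional Gaussian clusters (classes 1 and 2), plus `n_planted`
#' points drawn from class 1's distribution but labelled 2 — ground-truth
#' noise whose indices are returned so removal recall is measurable.
#'
#' @param n_per_class Samples per clean cluster.
#' @param n_planted Number of mislabelled points (must be < `n_per_class`).
#' @param seed Integer seed.
#' @param separation Distance between cluster centres in units of the
#'   within-cluster standard deviation (default 10).
#' @return List with `dataset` (an `hrv_dataset`) and `planted`
#'   (integer row indices of the mislabelled points).
#' @export
planted_boundary_cohort <- function(n_per_class, n_planted = 0L, seed = 1L,
                                    separation = 10) {
  stopifnot(n_planted < n_per_class, n_per_class >= 2)
  p <- 9L
  mu2 <- rep(separation / sqrt(p), p)
  with_seed(seed, {
    x1 <- matrix(stats::rnorm(n_per_class * p), n_per_class, p)
    x2 <- matrix(stats::rnorm(n_per_class * p), n_per_class, p)
    x2 <- sweep(x2, 2, mu2, "+")
    planted_x <- if (n_planted > 0)
      matrix(stats::rnorm(n_planted * p), n_planted, p) else
      matrix(numeric(0), 0, p)
    feats <- rbind(x1, x2, planted_x)
    labels <- c(rep(1L, n_per_class), rep(2L, n_per_class),
                rep(2L, n_planted))
    ds <- hrv_dataset(feats, labels, feature_names = paste0("V", 1:p),
                      label_set = c(1L, 2L))
    planted <- if (n_planted > 0)
      seq(2 * n_per_class + 1, length.out = n_planted) else integer(0)
    list(dataset = ds, planted = planted)
  })
}
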