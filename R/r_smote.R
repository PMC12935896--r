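#' Refined-SMOTE configuration
#'
#' Knobs of the refined SMOTE oversampler. Synthetic minority samples are
#' drawn either on the line through a seed sample and a same-class neighbour
#' (in-line, weight `lambda`) or on the sphere whose diameter is the
#' seed-neighbour segment (off-line, angle `theta`; by Thales' theorem every
#' such point sees the segment at a right angle).
#'
#' @param k_neighbors Number of same-class nearest neighbours per seed
#'   (default 3); clamped (with a warning) to class size minus 1.
#' @param lambda_range Closed interval within \[-1, 1\] for the in-line
#'   interpolation weight; negative values extrapolate beyond the seed.
#' @param theta_range Closed interval within \[-pi/2, pi/2\] (radians) for
#'   the off-line angle: theta = 0 lands on the neighbour, theta = +/- pi/2
#'   on the seed.
#' @param offline_probability Probability that a synthetic sample uses
#'   off-line rather than in-line interpolation (default 0.5).
#' @param per_class_targets Named vector/list mapping class label to desired
#'   post-oversampling count; `NULL` (default) targets the largest class's
#'   count for every class.
#' @param seed Integer seed for all random draws.
#' @return Object of class `smote_config`.
#' @examples
#' smote_config()                                  # refined defaults
#' classic_smote_config()                          # classic-SMOTE preset
#' @export
smote_config <- function(k_neighbors = 3L, lambda_range = c(-1, 1),
                         theta_range = c(-pi / 2, pi / 2),
                         offline_probability = 0.5,
                         per_class_targets = NULL, seed = 1L) {
  stopifnot(k_neighbors >= 1, length(lambda_range) == 2,
            length(theta_range) == 2)
  lambda_range <- sort(as.numeric(lambda_range))
  theta_range <- sort(as.numeric(theta_range))
  if (lambda_range[1] < -1 || lambda_range[2] > 1)
    stop("lambda_range must lie within [-1, 1]")
  if (theta_range[1] < -pi / 2 - 1e-12 || theta_range[2] > pi / 2 + 1e-12)
    stop("theta_range must lie within [-pi/2, pi/2]")
  stopifnot(offline_probability >= 0, offline_probability <= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 lambda_range = lambda_range, theta_range = theta_range,
                 offline_probability = offline_probability,
                 per_class_targets = per_class_targets,
                 seed = as.integer(seed)),
            class = "smote_config")
}

#' @rdname smote_config
#' @param ... Overrides passed on to [smote_config()].
#' @details `classic_smote_config()` is the classic-SMOTE preset: in-line
#'   only, `lambda` restricted to \[0, 1\] so every synthetic sample lies on
#'   the closed seed-neighbour segment.
#' @export
classic_smote_config <- function(...) {
  smote_config(lambda_range = c(0, 1), offline_probability = 0, ...)
}

#' Euclidean distance between two feature vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("length mismatch: ", length(a), " vs ", length(b))
  sqrt(sum((a - b)^2))
}

#' Same-class nearest neighbours of a row
#'
#' Finds the `k` rows sharing the query row's class that are nearest in
#' Euclidean distance, excluding the query itself. Distance ties are broken
#' by lower row index; the result is in ascending distance order.
#'
#' @param ds A validated `hrv_dataset`.
#' @param index Query row index.
#' @param k Number of neighbours; the class must have at least `k + 1`
#'   members.
#' @return Integer vector of `k` row indices.
#' @export
find_same_class_neighbors <- function(ds, index, k) {
  cls <- ds$labels[index]
  members <- which(ds$labels == cls)
  members <- members[members != index]
  if (length(members) < k)
    stop("class ", cls, " has only ", length(members) + 1,
         " members; cannot find k = ", k, " neighbours")
  d <- sqrt(colSums((t(ds$features[members, , drop = FALSE]) -
                       ds$features[index, ])^2))
  members[order(d, members)[seq_len(k)]]
}

#' In-line interpolation
#'
#' Classic SMOTE-style synthesis on the line through `xi` and `xj`:
#' `xi + lam * (xj - xi)`. With `lam` in \[0, 1\] the result lies on the
#' closed segment; negative `lam` extrapolates behind `xi`.
#'
#' @param xi,xj Numeric vectors of equal length (seed and neighbour).
#' @param lam Interpolation weight.
#' @return Numeric vector collinear with `xi` and `xj`.
#' @export
inline_interpolate <- function(xi, xj, lam) {
  if (length(xi) != length(xj))
    stop("length mismatch: ", length(xi), " vs ", length(xj))
  xi + lam * (xj - xi)
}

#' Off-line (Thales-circle) interpolation
#'
#' Synthesises a point on the sphere whose diameter is the segment from `xi`
#' to `xj`. Writing `d = ||xj - xi||`, `e_par = (xj - xi)/d` and `e_perp` a
#' unit vector orthogonal to `e_par`, the point is
#' `xi + d*cos(theta) * (cos(theta)*e_par + sin(theta)*e_perp)`, so its
#' distance from the seed is `d*cos(theta)`, `theta = 0` recovers `xj`, and
#' `theta = +/- pi/2` recovers `xi`. By Thales' theorem
#' `(x - xi) . (x - xj) = 0`. In two dimensions, with `e_perp` the clockwise
#' 90-degree rotation of `e_par`, this reproduces the planar
#' `(d cos(theta) cos(phi), d cos(theta) sin(phi))` construction with
#' `phi = atan2(xj2 - xi2, xj1 - xi1) - theta`.
#'
#' @param xi,xj Distinct numeric vectors of equal length.
#' @param theta Angle in \[-pi/2, pi/2\].
#' @param perp_direction Unit vector orthogonal to `xj - xi` (within 1e-9).
#' @return Numeric vector on the Thales sphere.
#' @export
offline_interpolate <- function(xi, xj, theta, perp_direction) {
  if (length(xi) != length(xj))
    stop("length mismatch: ", length(xi), " vs ", length(xj))
  delta <- xj - xi
  d <- sqrt(sum(delta^2))
  if (d == 0) stop("xi and xj coincide; the Thales sphere is degenerate")
  if (abs(theta) > pi / 2 + 1e-12) stop("theta outside [-pi/2, pi/2]")
  e_par <- delta / d
  if (abs(sqrt(sum(perp_direction^2)) - 1) > 1e-9)
    stop("perp_direction is not unit norm")
  if (abs(sum(perp_direction * e_par)) > 1e-9)
    stop("perp_direction is not orthogonal to xj - xi")
  xi + d * cos(theta) * (cos(theta) * e_par + sin(theta) * perp_direction)
}

# Isotropic random unit vector orthogonal to `v` (consumes RNG state).
random_perp_direction <- function(v) {
  e_par <- v / sqrt(sum(v^2))
  repeat {
    r <- stats::rnorm(length(v))
    r <- r - sum(r * e_par) * e_par
    nr <- sqrt(sum(r^2))
    if (nr >= 1e-12) return(r / nr)
  }
}

# Clockwise 90-degree rotation, the canonical e_perp in 2-D.
rotate_clockwise_2d <- function(v) c(v[2], -v[1])

#' Generate synthetic minority samples (refined SMOTE)
#'
#' Brings each class up to its target count by appending synthetic rows.
#' Seeds cycle round-robin over the class's original rows; for each synthetic
#' row a neighbour is drawn uniformly from the seed's `k` same-class nearest
#' neighbours, the interpolation mode is Bernoulli(`offline_probability`),
#' and `lambda` / `theta` are uniform on their configured ranges. The
#' off-line perpendicular direction is an isotropic random unit vector
#' orthogonal to the seed-neighbour axis. Original rows are retained
#' unchanged; provenance tags record the mode. Same seed, same output.
#'
#' Interpolation assumes features on comparable scales; the resampling
#' pipeline standardises before calling this and inverts afterwards.
#'
#' @param ds A validated `hrv_dataset`.
#' @param cfg A [smote_config()].
#' @return A new `hrv_dataset` with `sum(pmax(0, target - count))` appended
#'   rows.
#' @export
generate_synthetic <- function(ds, cfg = smote_config()) {
  validate_hrv_dataset(ds)
  stopifnot(inherits(cfg, "smote_config"))
  counts <- table(factor(ds$labels, levels = ds$label_set))
  present <- as.integer(names(counts))[counts > 0]
  targets <- resolve_targets(cfg$per_class_targets, counts)
  new_feats <- list(); new_labels <- integer(0); new_prov <- character(0)
  with_seed(cfg$seed, {
    for (cls in present) {
      cur <- as.integer(counts[as.character(cls)])
      tgt <- targets[as.character(cls)]
      n_new <- tgt - cur
      if (n_new <= 0) next
      if (cur == 1)
        stop("class ", cls, " has a single member; no neighbour exists for ",
             "oversampling")
      k <- cfg$k_neighbors
      if (k >= cur) {
        warning("class ", cls, ": k_neighbors = ", k, " clamped to ", cur - 1)
        k <- cur - 1L
      }
      members <- which(ds$labels == cls)
      neigh <- lapply(members, function(i) find_same_class_neighbors(ds, i, k))
      rows <- matrix(NA_real_, n_new, ncol(ds$features))
      prov <- character(n_new)
      for (s in seq_len(n_new)) {
        seed_pos <- ((s - 1) %% cur) + 1
        xi <- ds$features[members[seed_pos], ]
        nb <- neigh[[seed_pos]][sample.int(k, 1)]
        xj <- ds$features[nb, ]
        offline <- stats::runif(1) < cfg$offline_probability
        if (offline && !all(xi == xj)) {
          theta <- stats::runif(1, cfg$theta_range[1], cfg$theta_range[2])
          e_perp <- random_perp_direction(xj - xi)
          rows[s, ] <- offline_interpolate(xi, xj, theta, e_perp)
          prov[s] <- "synthetic_offline"
        } else {
          lam <- stats::runif(1, cfg$lambda_range[1], cfg$lambda_range[2])
          rows[s, ] <- inline_interpolate(xi, xj, lam)
          prov[s] <- "synthetic_inline"
        }
      }
      new_feats[[length(new_feats) + 1]] <- rows
      new_labels <- c(new_labels, rep(cls, n_new))
      new_prov <- c(new_prov, prov)
    }
  })
  if (!length(new_feats)) return(ds)
  bind_rows_hrv(ds, do.call(rbind, new_feats), new_labels, new_prov)
}

# Resolve per-class targets: default every present class to the largest
# class's count; validate user-supplied targets against current counts.
resolve_targets <- function(per_class_targets, counts) {
  present <- names(counts)[counts > 0]
  if (is.null(per_class_targets)) {
    tgt <- stats::setNames(rep(max(counts), length(present)), present)
  } else {
    supplied <- unlist(per_class_targets)
    tgt <- stats::setNames(as.integer(counts[present]), present)
    tgt[names(supplied)] <- as.integer(supplied)
  }
  for (cls in names(tgt))
    if (tgt[cls] < counts[cls])
      stop("target for class ", cls, " (", tgt[cls],
           ") is below its current count (", counts[cls], ")")
  tgt
}
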