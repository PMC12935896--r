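test_that("euclidean_distance matches hand values and is symmetric", {
  a <- rep(0, 9); b <- c(3, 4, rep(0, 7))
  expect_identical(euclidean_distance(a, b), 5)
  expect_identical(euclidean_distance(a, a), 0)
  expect_equal(euclidean_distance(rep(1, 9), rep(2, 9)), 3)
  expect_identical(euclidean_distance(a, b), euclidean_distance(b, a))
  expect_error(euclidean_distance(1:3, 1:4), "length mismatch")
})

test_that("same-class neighbour search honours class, order and tie rule", {
  # 3 same-class points on a line at 0, 1, 5 plus an off-class point at 0.1
  ds <- hrv_dataset(cbind(c(0, 1, 5, 0.1)), c(1, 1, 1, 2))
  expect_identical(find_same_class_neighbors(ds, 1, 1), 2L)
  expect_identical(find_same_class_neighbors(ds, 1, 2), c(2L, 3L))
  # equidistant candidates: lower index first
  ds2 <- hrv_dataset(cbind(c(0, -1, 1, 2)), rep(1L, 4))
  expect_identical(find_same_class_neighbors(ds2, 1, 2), c(2L, 3L))
  expect_error(find_same_class_neighbors(ds, 4, 1), "cannot find")
})

test_that("neighbour search matches a brute-force oracle on a random cohort", {
  ds <- random_dataset(30, p = 5, classes = 1:3, seed = 11)
  for (i in seq_len(30)) {
    cls <- ds$labels[i]
    members <- setdiff(which(ds$labels == cls), i)
    k <- min(3, length(members))
    if (k < 1) next
    d <- sapply(members, function(j)
      euclidean_distance(ds$features[i, ], ds$features[j, ]))
    expect_identical(find_same_class_neighbors(ds, i, k),
                     members[order(d, members)][seq_len(k)])
  }
})

test_that("in-line interpolation obeys its endpoint and midpoint identities", {
  xi <- c(1, 2, 3); xj <- c(4, 8, 6)
  expect_identical(inline_interpolate(xi, xj, 0), xi)
  expect_identical(inline_interpolate(xi, xj, 1), xj)
  expect_identical(inline_interpolate(c(0, 0), c(2, 4), 0.5), c(1, 2))
  expect_identical(inline_interpolate(xi, xj, -1), 2 * xi - xj)
})

test_that("off-line interpolation satisfies the Thales sphere contract", {
  # coincidence statements
  xi <- c(0, 0); xj <- c(2, 0); e_perp <- c(0, -1)
  expect_equal(offline_interpolate(xi, xj, 0, e_perp), xj)
  expect_equal(offline_interpolate(xi, xj, pi / 2, e_perp), xi)
  expect_equal(offline_interpolate(xi, xj, -pi / 2, e_perp), xi)
  # worked planar case: on circle centre (1,0) radius 1, |x - xi| = sqrt(2)
  x <- offline_interpolate(xi, xj, pi / 4, e_perp)
  expect_equal(x, c(1, -1))
  expect_equal(euclidean_distance(x, c(1, 0)), 1)
  expect_equal(euclidean_distance(x, xi), 2 * cos(pi / 4))
  # guards
  expect_error(offline_interpolate(xi, xi, 0.3, e_perp), "coincide")
  expect_error(offline_interpolate(xi, xj, 0.3, c(0, -2)), "unit norm")
  expect_error(offline_interpolate(xi, xj, 0.3, c(1, 0)), "not orthogonal")
})

test_that("off-line samples in 9-D satisfy orthogonality and distance invariants", {
  rsmoteenn:::with_seed(99, {
    for (rep in 1:500) {
      xi <- rnorm(9); xj <- rnorm(9)
      theta <- runif(1, -pi / 2, pi / 2)
      e_perp <- rsmoteenn:::random_perp_direction(xj - xi)
      x <- offline_interpolate(xi, xj, theta, e_perp)
      d <- euclidean_distance(xi, xj)
      expect_lt(abs(sum((x - xi) * (x - xj))), 1e-9 * d^2)
      expect_equal(euclidean_distance(x, xi), d * cos(theta),
                   tolerance = 1e-9)
      # on the sphere with centre (xi+xj)/2, radius d/2
      expect_equal(euclidean_distance(x, (xi + xj) / 2), d / 2,
                   tolerance = 1e-9)
    }
  })
})

test_that("general construction reduces to the planar formula in 2-D", {
  # planar reference: phi = atan2(xj2-xi2, xj1-xi1) - theta
  planar <- function(xi, xj, theta) {
    d <- euclidean_distance(xi, xj)
    phi <- atan2(xj[2] - xi[2], xj[1] - xi[1]) - theta
    xi + d * cos(theta) * c(cos(phi), sin(phi))
  }
  rsmoteenn:::with_seed(7, {
    for (rep in 1:1000) {
      xi <- rnorm(2); xj <- rnorm(2)
      if (all(xi == xj)) next
      theta <- runif(1, -pi / 2, pi / 2)
      e_par <- (xj - xi) / euclidean_distance(xi, xj)
      x <- offline_interpolate(xi, xj, theta,
                               rsmoteenn:::rotate_clockwise_2d(e_par))
      expect_equal(x, planar(xi, xj, theta), tolerance = 1e-12)
    }
  })
})

test_that("smote_config validates its ranges", {
  expect_error(smote_config(lambda_range = c(-2, 1)), "within")
  expect_error(smote_config(theta_range = c(-2, 2)), "within")
  expect_error(smote_config(offline_probability = 1.5))
  expect_s3_class(classic_smote_config(), "smote_config")
  expect_identical(classic_smote_config()$offline_probability, 0)
})

test_that("generate_synthetic hits per-class targets and conserves counts", {
  ds <- imbalanced_pair_cohort(seed = 2)
  s <- fit_standardizer(ds)
  z <- apply_standardizer(ds, s)
  out <- generate_synthetic(z, smote_config(seed = 3))
  expect_identical(n_samples(out), 390L)  # both classes at 195
  expect_identical(sum(out$provenance != "original"), 189L)
  expect_identical(out$labels[out$provenance != "original"], rep(2L, 189))
  # original rows unchanged and first
  expect_identical(out$features[seq_len(n_samples(z)), ], z$features)
  # no-op when targets equal counts
  tgt <- list(`2` = 6L, `4` = 195L)
  same <- generate_synthetic(z, smote_config(per_class_targets = tgt))
  expect_identical(same$features, z$features)
  # target below count rejected
  expect_error(generate_synthetic(z, smote_config(per_class_targets =
                                                    list(`4` = 100L))),
               "below its current count")
})

test_that("classic preset keeps synthetic rows on the seed-neighbour segment", {
  ds <- two_cluster_dataset(n_per_class = 8, p = 4, seed = 5)
  # make class 1 the minority
  ds <- subset_rows(ds, c(1:4, 9:16))
  out <- generate_synthetic(ds, classic_smote_config(seed = 6))
  synth <- which(out$provenance != "original")
  expect_true(all(out$provenance[synth] == "synthetic_inline"))
  orig1 <- which(out$labels == 1 & out$provenance == "original")
  for (i in synth) {
    x <- out$features[i, ]
    ok <- FALSE
    for (a in orig1) for (b in setdiff(orig1, a)) {
      xa <- out$features[a, ]; xb <- out$features[b, ]
      seg <- xb - xa
      t <- sum((x - xa) * seg) / sum(seg^2)
      resid <- x - (xa + t * seg)
      if (t >= -1e-9 && t <= 1 + 1e-9 && sqrt(sum(resid^2)) < 1e-8) ok <- TRUE
    }
    expect_true(ok)
  }
})

test_that("synthetic generation is deterministic in the seed", {
  ds <- imbalanced_pair_cohort(seed = 4)
  a <- generate_synthetic(ds, smote_config(seed = 10))
  b <- generate_synthetic(ds, smote_config(seed = 10))
  c <- generate_synthetic(ds, smote_config(seed = 11))
  expect_identical(a$features, b$features)
  expect_identical(a$provenance, b$provenance)
  expect_false(identical(a$features, c$features))
})

test_that("oversampling a singleton class is rejected and k is clamped", {
  ds <- hrv_dataset(matrix(rnorm(10), 5, 2), c(1L, 2L, 2L, 2L, 2L))
  expect_error(generate_synthetic(ds, smote_config(per_class_targets =
                                                     list(`1` = 3L))),
               "single member")
  ds2 <- hrv_dataset(matrix(rnorm(14), 7, 2), c(1L, 1L, rep(2L, 5)))
  expect_warning(out <- generate_synthetic(ds2, smote_config(seed = 1)),
                 "clamped")
  expect_identical(n_samples(out), 10L)
})
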