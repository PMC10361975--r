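test_that("PCA intermediate map matches the closed-form rank-1 solution", {
  t <- seq(-2, 2, length.out = 11)
  X <- cbind(x = t + 5, y = 2 * t + 1)      # points on y = 2x shifted
  f <- fit_intermediate_map(X, "pca", l = 1)
  expect_equal(as.numeric(f$P), c(1, 2) / sqrt(5), tolerance = 1e-10)
  expect_equal(f$center, c(5, 1), tolerance = 1e-10)
  # orthonormal columns
  expect_equal(crossprod(f$P), diag(1), tolerance = 1e-10)
})

test_that("projection is lossless at full rank and rejects invalid l", {
  set.seed(1)
  B <- matrix(rnorm(20 * 3), 20, 3)
  W <- matrix(rnorm(3 * 6), 3, 6)
  X <- B %*% W                               # rank 3 in 6 dimensions
  f <- fit_intermediate_map(X, "pca", l = 3)
  Xt <- apply_map(f, X)
  back <- sweep(Xt %*% t(f$P), 2, -f$center)
  expect_equal(back, X, tolerance = 1e-8)

  expect_error(fit_intermediate_map(X, "pca", l = 6), "l < d")
  expect_error(fit_intermediate_map(X, "pca", l = 7), "l < d")
  expect_error(fit_intermediate_map(X, "pca", l = 5), "rank")
  expect_error(fit_intermediate_map(X[1, , drop = FALSE], "pca", l = 2),
               "2 samples")
})

test_that("applying a map centres correctly and preserves in-span geometry", {
  set.seed(2)
  d <- 5
  f <- fit_intermediate_map(matrix(rnorm(30 * d), 30, d), "pca", l = 3)
  # replicated centre maps to the origin
  X0 <- matrix(f$center, 4, d, byrow = TRUE)
  expect_equal(apply_map(f, X0), matrix(0, 4, 3), tolerance = 1e-10)

  # svd map on data lying in an (d-1)-dim subspace: orthonormal projection
  # onto its own span is an isometry
  B <- matrix(rnorm(40 * (d - 1)), 40, d - 1)
  W <- qr.Q(qr(matrix(rnorm(d * d), d, d)))[, 1:(d - 1)]
  X <- B %*% t(W)
  fs <- fit_intermediate_map(X, "svd", l = d - 1)
  Xt <- apply_map(fs, X)
  expect_equal(as.matrix(dist(Xt)), as.matrix(dist(X)), tolerance = 1e-8)

  expect_error(apply_map(f, matrix(0, 2, d + 1)), "dimension mismatch")
})

test_that("scaled maps standardise columns before projecting", {
  set.seed(3)
  X <- cbind(a = rnorm(50, 0, 100), b = rnorm(50, 5, 0.1), c = rnorm(50))
  f <- fit_intermediate_map(X, "pca", l = 2, scale. = TRUE)
  expect_equal(f$scale, unname(apply(X, 2, sd)), tolerance = 1e-12)
  # unscaled PCA is dominated by the high-variance column
  f0 <- fit_intermediate_map(X, "pca", l = 1)
  expect_gt(abs(f0$P[1, 1]), 0.99)
  # after scaling no column dominates by construction
  expect_lt(max(abs(f$P[, 1])), 0.99)
})

test_that("anchor generation respects bounds, seeds, and convexity", {
  bounds <- list(a = c(0, 1), b = c(-2, -1), c = c(10, 20))
  a1 <- generate_anchor(bounds, r = 200, seed = 5)
  a2 <- generate_anchor(bounds, r = 200, seed = 5)
  expect_identical(a1$A, a2$A)
  expect_equal(dim(a1$A), c(200, 3))
  expect_true(all(a1$A[, "a"] >= 0 & a1$A[, "a"] <= 1))
  expect_true(all(a1$A[, "b"] >= -2 & a1$A[, "b"] <= -1))
  expect_true(all(a1$A[, "c"] >= 10 & a1$A[, "c"] <= 20))

  expect_error(generate_anchor(list(a = c(1, 0)), r = 5), "lo < hi")
  expect_error(generate_anchor(NULL, r = 5, strategy = "uniform"), "bounds")

  # SMOTE-style resampling from a 2-row table stays on the segment
  ref <- rbind(c(0, 0, 0), c(1, 2, 4))
  ar <- generate_anchor(strategy = "resample", reference = ref, r = 100,
                        seed = 6)
  w <- ar$A[, 1]
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(ar$A[, 2], 2 * w, tolerance = 1e-12)
  expect_equal(ar$A[, 3], 4 * w, tolerance = 1e-12)

  # encoded column names map back to base-feature reference ranges
  b <- anchor_bounds(c("HbA1c_2014", "HbA1c_2015", "Sex", "Age"))
  expect_equal(b$HbA1c_2014, b$HbA1c_2015)
  expect_equal(b$Sex, c(0, 1))
  expect_error(anchor_bounds("Mystery_2014"), "no reference range")
})

test_that("collaboration maps match the brute-force least-squares oracle", {
  set.seed(11)
  for (case in 1:20) {
    n <- sample(2:3, 1)
    r <- sample(5:10, 1)
    ls <- sample(2:4, n, replace = TRUE)
    k <- min(ls)
    anchors <- lapply(ls, function(l) matrix(rnorm(r * l), r, l))
    g <- compute_collaboration_maps(anchors, k)
    for (i in seq_len(n)) {
      expect_lt(frob(g$maps[[i]] - ls_oracle(anchors[[i]], g$Z)), 1e-8)
    }
    # the shared target has orthonormal columns
    expect_equal(crossprod(g$Z), diag(k), tolerance = 1e-10)
  }
})

test_that("single orthonormal worker reproduces the target exactly", {
  set.seed(12)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  g <- compute_collaboration_maps(list(Q), k = 4)
  expect_equal(Q %*% g$maps[[1]], g$Z, tolerance = 1e-10)
  expect_equal(anchor_alignment_residual(g, list(Q)), 0)
})

test_that("identical workers get identical maps and zero residual", {
  set.seed(13)
  A <- matrix(rnorm(8 * 3), 8, 3)
  g <- compute_collaboration_maps(list(A, A), k = 3)
  expect_equal(g$maps[[1]], g$maps[[2]], tolerance = 1e-12)
  expect_lt(anchor_alignment_residual(g, list(A, A)), 1e-10)
})

test_that("least-squares optimality: any perturbation of a map increases
           its alignment error", {
  set.seed(14)
  anchors <- list(matrix(rnorm(6 * 2), 6, 2), matrix(rnorm(6 * 2), 6, 2))
  g <- compute_collaboration_maps(anchors, k = 2)
  base <- frob(anchors[[1]] %*% g$maps[[1]] - g$Z)
  for (i in 1:2) {
    for (j in 1:2) {
      G2 <- g$maps[[1]]
      G2[i, j] <- G2[i, j] + 1
      expect_gt(frob(anchors[[1]] %*% G2 - g$Z), base)
    }
  }
  # and the pairwise residual computed fresh also grows
  g2 <- g
  g2$maps[[1]][1, 1] <- g2$maps[[1]][1, 1] + 1
  expect_gt(anchor_alignment_residual(g2, anchors),
            anchor_alignment_residual(g, anchors))
})

test_that("heterogeneous worker dimensions integrate to a common k", {
  set.seed(15)
  ds <- lapply(c(5, 7), function(m) {
    X <- matrix(rnorm(m * 6), m, 6)
    list(X = X, y = rbinom(m, 1, 0.5), institution = paste0("w", m))
  })
  anchor <- generate_anchor(setNames(rep(list(c(-2, 2)), 6),
                                     paste0("f", 1:6)), r = 50, seed = 2)
  f1 <- fit_intermediate_map(ds[[1]]$X, "pca", l = 3)
  f2 <- fit_intermediate_map(ds[[2]]$X, "pca", l = 4)
  g <- compute_collaboration_maps(list(apply_map(f1, anchor),
                                       apply_map(f2, anchor)))
  expect_equal(g$k, 3)                      # min over worker dimensions
  collab <- build_collaborative_dataset(ds, list(f1, f2), g)
  expect_equal(dim(collab$X), c(12, 3))
  expect_equal(collab$provenance, rep(c("w5", "w7"), c(5, 7)))
  expect_equal(length(collab$y), 12)

  expect_error(compute_collaboration_maps(
    list(apply_map(f1, anchor), apply_map(f2, anchor)), k = 4), "exceeds")
  expect_error(compute_collaboration_maps(
    list(matrix(0, 5, 2), matrix(0, 6, 2))), "share the anchor count")
  expect_error(compute_collaboration_maps(
    list(cbind(1:5, 1:5))), "rank")
})

test_that("identity limit: duplicated worker yields equal collaborative
           blocks", {
  set.seed(16)
  X <- matrix(rnorm(30 * 5), 30, 5)
  ds <- list(X = X, y = rbinom(30, 1, 0.4), institution = "dup")
  anchor <- generate_anchor(setNames(rep(list(c(-3, 3)), 5),
                                     paste0("f", 1:5)), r = 100, seed = 3)
  w1 <- worker_encode(ds, anchor, l = 3, scale. = FALSE)
  w2 <- worker_encode(ds, anchor, l = 3, scale. = FALSE)
  mc <- master_collaborate(list(w1$share, w2$share))
  expect_lt(mc$residual, 1e-10)
  b1 <- mc$collab$X[1:30, ]
  b2 <- mc$collab$X[31:60, ]
  expect_equal(b1, b2, tolerance = 1e-10)
})

test_that("the master-facing surface never receives raw worker data", {
  set.seed(17)
  X <- matrix(rnorm(20 * 4), 20, 4)
  ds <- list(X = X, y = rbinom(20, 1, 0.5), institution = "w")
  anchor <- generate_anchor(setNames(rep(list(c(-3, 3)), 4),
                                     paste0("f", 1:4)), r = 30, seed = 4)
  wk <- worker_encode(ds, anchor, l = 2)
  # the transmitted share carries only compressed data, anchors, labels
  expect_setequal(names(wk$share),
                  c("intermediate", "anchor_intermediate", "y", "worker"))
  expect_equal(ncol(wk$share$intermediate), 2)
  expect_false(any(vapply(wk$share, identical, logical(1), ds$X)))
  # master entry points are defined over shares / intermediates only
  expect_setequal(names(formals(master_collaborate)), c("shares", "k"))
  expect_setequal(names(formals(compute_collaboration_maps)),
                  c("anchor_intermediates", "k"))
  # and the master output is reproducible from the share alone
  mc <- master_collaborate(list(wk$share))
  expect_equal(dim(mc$collab$X), c(20, 2))
})

test_that("map orientation is deterministic across refits", {
  set.seed(18)
  X <- matrix(rnorm(40 * 6), 40, 6)
  f1 <- fit_intermediate_map(X, "pca", l = 4)
  f2 <- fit_intermediate_map(X[sample(40), ], "pca", l = 4)
  # same data in permuted row order: identical principal directions
  expect_equal(f1$P, f2$P, tolerance = 1e-8)
  # each column's largest-magnitude entry is positive
  for (j in 1:4) expect_gt(f1$P[which.max(abs(f1$P[, j])), j], 0)
})
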