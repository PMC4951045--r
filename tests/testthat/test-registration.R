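# Trimmed point-to-point ICP and its building blocks.

test_that("match_nearest agrees with an exhaustive scan", {
  set.seed(5)
  src <- point_cloud(matrix(rnorm(600, sd = 10), 200, 3))
  tgt <- point_cloud(matrix(rnorm(900, sd = 10), 300, 3))
  corr <- match_nearest(src, tgt)
  bf <- bf_nearest(src$points, tgt$points)
  expect_identical(corr$target_idx, bf$index)
  expect_equal(corr$distances, bf$distance, tolerance = 1e-12)

  self <- match_nearest(tgt, tgt)
  expect_identical(self$target_idx, seq_len(300))
  expect_true(all(self$distances == 0))
})

test_that("equidistant matches resolve to the lower target index", {
  src <- point_cloud(matrix(c(0, 0, 0), 1, 3))
  tgt <- point_cloud(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0)))
  expect_identical(match_nearest(src, tgt)$target_idx, 1L)
  # same with the symmetric pair later in the list
  tgt2 <- point_cloud(rbind(c(5, 5, 5), c(0, 0, 1), c(0, 0, -1)))
  expect_identical(match_nearest(src, tgt2)$target_idx, 2L)
})

test_that("reject_worst clears exactly the largest-distance pairs", {
  mk <- function(d) structure(list(source_idx = seq_along(d),
                                   target_idx = seq_along(d), distances = d,
                                   kept = rep(TRUE, length(d))),
                              class = "correspondences")
  all_kept <- reject_worst(mk(runif(57)), 0)
  expect_true(all(all_kept$kept))

  ranks <- mk(sample(1:100))  # distances are a permutation of 1..100
  out <- reject_worst(ranks, 0.05)
  expect_identical(sum(out$kept), 95L)
  expect_setequal(ranks$distances[!out$kept], 96:100)

  set.seed(15)
  d <- runif(203)
  out <- reject_worst(mk(d), 0.05)
  expect_identical(sum(out$kept), as.integer(ceiling(0.95 * 203)))
  expect_setequal(which(!out$kept), order(d, decreasing = TRUE)[seq_len(floor(0.05 * 203))])
})

test_that("estimate_rigid_svd recovers exact rigid motions", {
  set.seed(25)
  src <- matrix(rnorm(120, sd = 30), 40, 3)
  expect_lt(max(abs(as_matrix(estimate_rigid_svd(src, src)) - diag(4))), 1e-12)
  R0 <- rand_rot(); t0 <- rnorm(3, sd = 50)
  tgt <- src %*% t(R0) + rep(1, 40) %o% t0
  est <- estimate_rigid_svd(src, tgt)
  expect_lt(max(abs(est$rotation - R0)), 1e-10)
  expect_lt(max(abs(est$translation - t0)), 1e-10)
  expect_error(estimate_rigid_svd(src[1:2, ], tgt[1:2, ]), "3 point")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(estimate_rigid_svd(line, line %*% t(R0)), "collinear")
})

test_that("reflected targets never produce det(R) = -1", {
  set.seed(35)
  src <- cbind(rnorm(50, sd = 20), rnorm(50, sd = 20), rnorm(50, sd = 0.1))
  tgt <- src %*% diag(c(1, 1, -1))  # mirror of a planar-ish cloud
  est <- estimate_rigid_svd(src, tgt)
  expect_gt(det(est$rotation), 0.999)
})

test_that("icp recovers ground-truth motion on noiseless full overlap", {
  for (seed in 1:3) {
    set.seed(seed)
    src <- phantom_cloud(600, seed = seed, frame = "S")
    R0 <- rand_rot_bounded(20 * pi / 180)
    t0 <- runif(3, -30, 30)
    tgt <- point_cloud(src$points %*% t(R0) + rep(1, 600) %o% t0, "T")
    res <- icp(src, tgt, trim = 0)  # outlier-free: rejection off
    expect_true(res$converged)
    expect_lt(rot_angle(res$transform$rotation, R0), 1e-6)
    expect_lt(max(abs(res$transform$translation - t0)), 1e-4)
  }
})

test_that("icp on identical clouds converges immediately to zero RMSE", {
  cl <- phantom_cloud(300, seed = 4, frame = "G")
  res <- icp(cl, cl)
  expect_identical(res$iterations, 1L)
  expect_identical(res$rmse_history, 0)
  expect_true(res$converged)
  expect_lt(max(abs(as_matrix(res$transform) - diag(4))), 1e-12)
})

test_that("icp RMSE history is non-increasing", {
  set.seed(45)
  src <- phantom_cloud(500, seed = 6, frame = "S")
  R0 <- rand_rot_bounded(15 * pi / 180)
  tgt <- point_cloud(src$points %*% t(R0) + 10 +
                       matrix(rnorm(1500, sd = 0.5), 500, 3), "T")
  res <- icp(src, tgt)
  expect_true(all(diff(res$rmse_history) <= 1e-9))
})

test_that("noiseless symmetric registrations are mutually inverse", {
  set.seed(55)
  A <- phantom_cloud(500, seed = 8, frame = "A")
  R0 <- rand_rot_bounded(15 * pi / 180); t0 <- runif(3, -20, 20)
  B <- point_cloud(A$points %*% t(R0) + rep(1, 500) %o% t0, "B")
  fwd <- icp(A, B, trim = 0)$transform
  bwd <- icp(B, A, trim = 0)$transform
  round_trip <- compose_transforms(bwd, fwd)
  expect_lt(rot_angle(round_trip$rotation), 1e-6)
  expect_lt(max(abs(round_trip$translation)), 1e-4)
})

test_that("icp validates frames and degenerate input", {
  A <- point_cloud(matrix(rnorm(30), 10, 3), "A")
  B <- point_cloud(matrix(rnorm(30), 10, 3), "B")
  bad_init <- rigid_transform(diag(3), c(0, 0, 0), "X", "B")
  expect_error(icp(A, B, init = bad_init), "init maps")
  expect_error(icp(point_cloud(matrix(rnorm(6), 2, 3), "A"), B), "3 points")
})
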