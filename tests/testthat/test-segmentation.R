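# Otsu thresholding, CT surface extraction, WFCM, ToF segmentation.

test_that("otsu separates two delta classes and matches exhaustive search", {
  x <- c(rep(-1000, 500), rep(0, 500))
  th <- otsu_threshold(array(x, c(10, 10, 10)))
  expect_gt(th, -1000)
  expect_lt(th, 0)
  expect_error(otsu_threshold(array(5, c(3, 3, 3))), "constant")

  # exhaustive between-class-variance oracle with identical tie handling
  set.seed(8)
  v <- c(rnorm(5000, -1000, 30), rnorm(800, 0, 50))
  th <- otsu_threshold(v)
  nb <- 256
  br <- seq(min(v), max(v), length.out = nb + 1)
  cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nb)
  best <- -1; arg <- integer(0)  # between-class variance is non-negative
  for (i in 1:(nb - 1)) {
    n1 <- sum(cnt[1:i]); n2 <- sum(cnt) - n1
    if (n1 == 0 || n2 == 0) next
    mids <- (br[-1] + br[-(nb + 1)]) / 2
    m1 <- sum(cnt[1:i] * mids[1:i]) / n1
    m2 <- sum(cnt[(i + 1):nb] * mids[(i + 1):nb]) / n2
    sb <- (n1 / sum(cnt)) * (n2 / sum(cnt)) * (m1 - m2)^2
    if (sb > best + 1e-12 * abs(best)) { best <- sb; arg <- i }
    else if (sb >= best - 1e-12 * abs(best)) arg <- c(arg, i)
  }
  expected <- br[1] + mean(arg) * (br[2] - br[1])
  expect_equal(th, expected, tolerance = 1e-9)
})

test_that("segment_ct recovers an analytic sphere surface", {
  mesh <- make_phantom("sphere")
  vol <- voxelize_ct(mesh, spacing = 1, seed = 5)
  surf <- segment_ct(vol)
  expect_gt(n_points(surf), 0)
  expect_identical(surf$frame, "CT")
  err <- abs(sqrt(rowSums(surf$points^2)) - 40)
  expect_lt(max(err), sqrt(3))  # within one voxel diagonal
})

test_that("disconnected specks are removed by the largest-component rule", {
  dims <- c(40, 40, 40)
  hu <- array(-1000, dims)
  ax <- seq(-19.5, 19.5)
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  hu[r2 <= 12^2] <- 50
  hu[2:3, 2, 2] <- 50  # 2-voxel speck far from the ball
  vol <- ct_volume(hu)
  surf <- segment_ct(vol, close_radius = 0)
  ctr <- (c(40, 40, 40) - 1) / 2
  d <- sqrt(rowSums(sweep(surf$points, 2, ctr)^2))
  expect_true(all(d > 8))        # no speck-corner vertices near (1,1,1)
  expect_true(all(d < 12 + sqrt(3)))
  corner <- sqrt(rowSums(sweep(surf$points, 2, c(1.5, 1, 1))^2))
  expect_true(all(corner > 5))
})

test_that("internal cavities are filled: only the outer surface remains", {
  dims <- c(50, 50, 50)
  hu <- array(-1000, dims)
  ax <- seq(-24.5, 24.5)
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  hu[r2 <= 18^2 & r2 >= 9^2] <- 50   # hollow shell, cavity radius 9
  vol <- ct_volume(hu)
  surf <- segment_ct(vol, close_radius = 0)
  ctr <- (dims - 1) / 2
  d <- sqrt(rowSums(sweep(surf$points, 2, ctr)^2))
  expect_true(all(abs(d - 18) < sqrt(3)))  # no cavity wall at radius ~9
})

test_that("segment_ct is invariant under uniform air padding", {
  mesh <- make_phantom("sphere", radius = 20)
  vol <- voxelize_ct(mesh, spacing = 1, pad = 10, blur_sigma = 0, seed = 6)
  surf1 <- segment_ct(vol)
  padn <- 8
  dims <- dim(vol$data)
  big <- array(-1000, dims + 2 * padn)
  big[padn + seq_len(dims[1]), padn + seq_len(dims[2]),
      padn + seq_len(dims[3])] <- vol$data
  vol2 <- ct_volume(big, vol$spacing, vol$origin - padn * vol$spacing)
  surf2 <- segment_ct(vol2)
  expect_identical(n_points(surf1), n_points(surf2))
  o1 <- surf1$points[do.call(order, as.data.frame(surf1$points)), ]
  o2 <- surf2$points[do.call(order, as.data.frame(surf2$points)), ]
  expect_lt(max(abs(o1 - o2)), 1e-9)
})

test_that("wfcm finds two point masses with near-crisp memberships", {
  X <- rbind(matrix(rep(c(0, 0), 50), ncol = 2, byrow = TRUE),
             matrix(rep(c(10, 10), 50), ncol = 2, byrow = TRUE))
  lab <- wfcm(X, k = 2, seed = 3)
  C <- lab$centers[order(lab$centers[, 1]), ]
  expect_lt(max(abs(C - rbind(c(0, 0), c(10, 10)))), 1e-6)
  expect_true(all(apply(lab$memberships, 1, max) >= 0.99))
  expect_true(all(rowSums(lab$memberships) - 1 < 1e-9))
  expect_identical(lab$labels, max.col(lab$memberships))
})

test_that("equal-weight wfcm matches an unweighted FCM oracle", {
  set.seed(13)
  X <- rbind(matrix(rnorm(160, 0, 1), ncol = 2),
             matrix(rnorm(140, 6, 1), ncol = 2))
  lab <- wfcm(X, k = 2, seed = 7, tol = 1e-10)
  oracle <- bf_fcm(X, lab$initial_centers, m = 2, tol = 1e-10)
  expect_lt(max(abs(lab$centers - oracle)), 1e-8)
})

test_that("a dominant weight pins a cluster centre", {
  set.seed(23)
  X <- matrix(runif(200, 0, 10), ncol = 2)
  X[1, ] <- c(20, 20)
  w <- rep(1, 100); w[1] <- 1e6
  lab <- wfcm(X, weights = w, k = 2, seed = 5)
  expect_lt(min(sqrt(rowSums(sweep(lab$centers, 2, c(20, 20))^2))), 1e-3)
})

test_that("the wfcm objective is non-increasing", {
  set.seed(33)
  X <- matrix(rnorm(600), ncol = 3)
  lab <- wfcm(X, weights = runif(200, 0.2, 1), k = 3, seed = 11)
  expect_true(all(diff(lab$objective) <= 1e-9 * abs(lab$objective[-1]) + 1e-12))
})

test_that("wfcm validates its inputs", {
  X <- matrix(rnorm(60), ncol = 3)
  expect_error(wfcm(X, weights = rep(0, 20)), "weights")
  expect_error(wfcm(X, k = 1), "k >= 2")
  expect_error(wfcm(X, m = 1), "m > 1")
})

test_that("segment_tof isolates the object in a separable scene", {
  # constructed noise-free frame: a bright near block against a dim far
  # background, fully separable in depth and amplitude
  H <- 24; W <- 32
  mask <- matrix(FALSE, H, W)
  mask[8:16, 10:22] <- TRUE
  z <- ifelse(mask, 700, 1100)
  xyz <- array(0, c(H, W, 3))
  xyz[, , 1] <- outer(rep(1, H), seq_len(W) - W / 2) * 4
  xyz[, , 2] <- outer(seq_len(H) - H / 2, rep(1, W)) * 4
  xyz[, , 3] <- z
  amp <- ifelse(mask, 0.9, 0.15)
  conf <- ifelse(mask, 0.95, 0.5)
  fr <- depth_frame(xyz, amp, conf)
  seg <- segment_tof(fr, confidence_min = 0.3, seed = 1)
  pred <- matrix(FALSE, H, W)
  pred[attr(seg, "pixel_index")] <- TRUE
  expect_identical(pred, mask)
  expect_identical(seg$frame, "C")
  expect_identical(n_points(seg), sum(mask))
})

test_that("flying pixels never pass the confidence gate", {
  mesh <- make_phantom("sphere")
  sim <- simulate_tof(mesh, seed = 4)
  expect_gt(sum(sim$truth$flying), 0)
  seg <- segment_tof(sim$frame, confidence_min = 0.3, seed = 1)
  flying_idx <- which(sim$truth$flying)
  expect_length(intersect(attr(seg, "pixel_index"), flying_idx), 0)
})

test_that("segment_tof is equivariant under coordinate relabelling", {
  # a transform that permutes/negates axes and translates preserves the
  # per-dimension standardization, so the clustering must be unchanged
  mesh <- make_phantom("sphere")
  sim <- simulate_tof(mesh, seed = 6)
  seg1 <- segment_tof(sim$frame, seed = 1)
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  t0 <- c(15, -40, 120)
  fr2 <- sim$frame
  xyz <- matrix(fr2$xyz, 144 * 176, 3) %*% t(R) + rep(1, 144 * 176) %o% t0
  fr2$xyz <- array(xyz, dim(fr2$xyz))
  seg2 <- segment_tof(fr2, seed = 1)
  expect_identical(attr(seg1, "pixel_index"), attr(seg2, "pixel_index"))
  back <- sweep(seg2$points, 2, t0) %*% R
  expect_lt(max(abs(back - seg1$points)), 1e-6)
})
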