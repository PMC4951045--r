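# Pinhole model, distortion, Zhang calibration, PnP, projection validation.

tof_intr <- function(dist = rep(0, 5)) camera_intrinsics(250, 250, 88, 72, dist)

test_that("projection reduces to similar triangles on the optical axis", {
  intr <- camera_intrinsics(1, 1, 88, 72)   # unit focal length
  ext <- rt_identity("C")
  uv <- project_points(intr, ext, matrix(c(0, 0, 1), 1, 3))
  expect_equal(as.numeric(uv), c(88, 72), tolerance = 1e-12)
  uv <- project_points(intr, ext, matrix(c(1, 0, 2), 1, 3))
  expect_equal(as.numeric(uv) - c(88, 72), c(0.5, 0), tolerance = 1e-12)
})

test_that("projection matches the homogeneous-matrix oracle", {
  set.seed(3)
  intr <- tof_intr()
  R <- rand_rot_bounded(0.3); t <- c(10, -20, 700)
  ext <- rigid_transform(R, t, "G", "C")
  pts <- matrix(rnorm(60, sd = 60), 20, 3)
  uv <- project_points(intr, ext, pts)
  oracle <- bf_project(250, 250, 88, 72, R, t, pts)
  expect_lt(max(abs(uv - oracle)), 1e-9)
})

test_that("projection is invariant along the viewing ray", {
  intr <- tof_intr(c(0.1, -0.02, 0.001, -0.001, 0))
  ext <- rt_identity("C")
  d <- c(0.11, -0.07, 1)
  uv <- project_points(intr, ext, rbind(d * 300, d * 750, d * 1500))
  expect_lt(max(abs(sweep(uv, 2, uv[1, ]))), 1e-9)
})

test_that("points behind the camera are a projection error", {
  expect_error(project_points(tof_intr(), rt_identity("C"),
                              rbind(c(0, 0, 500), c(0, 0, -10))),
               "non-positive depth")
})

test_that("undistortion inverts the forward distortion model", {
  # zero distortion: exact pinhole inverse
  intr0 <- tof_intr()
  px <- cbind(runif(20, 0, 176), runif(20, 0, 144))
  xy <- undistort_pixels(intr0, px)
  expect_lt(max(abs(xy[, 1] * 250 + 88 - px[, 1])), 1e-12)

  for (k1 in c(0.1, -0.2)) {
    intr <- tof_intr(c(k1, 0, 0, 0, 0))
    corner <- rbind(c(1, 1), c(175, 143), c(88, 72), c(10, 140))
    xy <- undistort_pixels(intr, corner)
    xyd <- surfreg:::distort_normalized(intr, xy)
    back <- cbind(xyd[, 1] * 250 + 88, xyd[, 2] * 250 + 72)
    expect_lt(max(abs(back - corner)), 1e-5)
  }
})

test_that("Zhang calibration recovers intrinsics from noiseless views", {
  views <- make_chessboard_views(n_views = 6, noise_px = 0, seed = 2)
  intr <- calibrate_intrinsics(views$observations)
  expect_lt(abs(intr$fx - 250) / 250, 0.005)
  expect_lt(abs(intr$fy - 250) / 250, 0.005)
  expect_lt(abs(intr$cx - 88), 0.5)
  expect_lt(abs(intr$cy - 72), 0.5)
  expect_lt(attr(intr, "rms_px"), 1e-8)
  expect_error(calibrate_intrinsics(views$observations[1:2]), "3 views")
})

test_that("calibration stays within 2% under corner noise", {
  fx <- sapply(1:5, function(s) {
    views <- make_chessboard_views(n_views = 8, noise_px = 0.1, seed = 100 + s)
    calibrate_intrinsics(views$observations)$fx
  })
  expect_true(all(abs(fx - 250) / 250 < 0.02))
})

test_that("PnP recovers noiseless poses exactly and rejects degenerate input", {
  views <- make_chessboard_views(n_views = 3, noise_px = 0, seed = 12)
  intr <- views$intr
  for (i in seq_along(views$observations)) {
    ob <- views$observations[[i]]
    est <- solve_pnp(intr, ob$corners_3d, ob$corners_2d)
    truth <- views$poses[[i]]
    expect_lt(rot_angle(est$rotation, truth$rotation), 1e-6)
    expect_lt(max(abs(est$translation - truth$translation)), 1e-4)
  }
  ob <- views$observations[[1]]
  expect_error(solve_pnp(intr, point_cloud(ob$corners_3d$points[1:5, ], "board"),
                         ob$corners_2d[1:5, ]), "6 correspondences")
  line <- point_cloud(cbind(1:10, 0, 0), "board")
  expect_error(solve_pnp(intr, line, cbind(1:10, 5)), "collinear")
})

test_that("PnP also solves non-planar configurations via DLT", {
  set.seed(9)
  intr <- tof_intr()
  pts <- point_cloud(matrix(rnorm(60, sd = 80), 20, 3), "G")
  R0 <- rand_rot_bounded(0.4); t0 <- c(20, -10, 900)
  truth <- rigid_transform(R0, t0, "G", "C")
  uv <- project_points(intr, truth, pts)
  est <- solve_pnp(intr, pts, uv)
  expect_lt(rot_angle(est$rotation, R0), 1e-6)
  expect_lt(max(abs(est$translation - t0)), 1e-4)
})

test_that("PnP reprojection error stays below 0.5 px under 0.2 px noise", {
  errs <- sapply(1:20, function(s) {
    views <- make_chessboard_views(n_views = 1, noise_px = 0.2, seed = 300 + s)
    ob <- views$observations[[1]]
    est <- solve_pnp(views$intr, ob$corners_3d, ob$corners_2d)
    attr(est, "rms_px")
  })
  expect_lt(mean(errs), 0.5)
})

test_that("validate_projection reports exact and constructed errors", {
  views <- make_chessboard_views(n_views = 1, noise_px = 0, seed = 22)
  ob <- views$observations[[1]]
  pose <- views$poses[[1]]
  rep0 <- validate_projection(views$intr, pose, ob$corners_3d, ob$corners_2d)
  expect_lt(rep0$mean_error, 1e-9)
  off <- ob$corners_2d
  off[, 1] <- off[, 1] + 1
  rep1 <- validate_projection(views$intr, pose, ob$corners_3d, off)
  expect_equal(rep1$mean_error, 1, tolerance = 1e-12)
  expect_equal(rep1$std_error, 0, tolerance = 1e-12)
  # mean/std consistency with the per-point vector
  expect_equal(rep1$mean_error, mean(rep1$per_point_error), tolerance = 1e-12)
})

test_that("validation through the composed marker chain matches direct validation", {
  # marker-frame test points validated directly vs via a composed global pose
  views <- make_chessboard_views(n_views = 1, noise_px = 0, seed = 32)
  ob <- views$observations[[1]]; pose <- views$poses[[1]]
  set.seed(33)
  T_Z_G <- rigid_transform(rand_rot(), rnorm(3, sd = 100), "Z", "G")
  # treat the board frame as marker frame Z
  pts_Z <- point_cloud(ob$corners_3d$points, "Z")
  extr_Z <- rigid_transform(pose$rotation, pose$translation, "Z", "C")
  pts_G <- apply_transform(T_Z_G, pts_Z)
  extr_G <- compose_transforms(extr_Z, invert_transform(T_Z_G))
  det <- ob$corners_2d
  r1 <- validate_projection(views$intr, extr_Z, pts_Z, det)
  r2 <- validate_projection(views$intr, extr_G, pts_G, det)
  expect_lt(max(abs(r1$per_point_error - r2$per_point_error)), 1e-9)
})

test_that("behind-camera validation points are excluded and flagged", {
  intr <- tof_intr()
  pts <- point_cloud(rbind(c(0, 0, 500), c(0, 0, -400)), "C")
  det <- rbind(c(88, 72), c(0, 0))
  rep <- validate_projection(intr, rt_identity("C"), pts, det)
  expect_identical(rep$excluded, 2L)
  expect_true(is.na(rep$per_point_error[2]))
  expect_lt(rep$mean_error, 1e-9)
})
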