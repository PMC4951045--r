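# Pinhole camera model with radial-tangential distortion, chessboard
# intrinsic calibration (Zhang's method), PnP pose estimation and the
# projection-error validation protocol used to assess depth-camera
# calibration against tracker-measured test points.

#' Camera intrinsic parameters
#'
#' Pixel convention: `(u, v)` with u rightward, v downward, origin at the
#' centre of the top-left pixel.  Distortion follows the 5-coefficient
#' radial-tangential model `(k1, k2, p1, p2, k3)` applied to normalized
#' image coordinates.
#'
#' @param fx,fy focal lengths (px), positive.
#' @param cx,cy principal point (px), inside the sensor.
#' @param dist length-5 distortion vector `(k1, k2, p1, p2, k3)`; default
#'   all zero.
#' @param width,height sensor size in pixels (default 176 x 144, the
#'   resolution class of compact ToF sensors).
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, dist = rep(0, 5),
                              width = 176, height = 144) {
  stopifnot(fx > 0, fy > 0, length(dist) == 5,
            cx > 0, cx < width, cy > 0, cy < height)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 dist = as.numeric(dist),
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics %dx%d: fx=%.3f fy=%.3f cx=%.3f cy=%.3f>\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  if (any(x$dist != 0))
    cat("  dist:", paste(signif(x$dist, 4), collapse = " "), "\n")
  invisible(x)
}

# Forward distortion on normalized coordinates (M x 2).
distort_normalized <- function(intr, xy) {
  k <- intr$dist
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + k[1] * r2 + k[2] * r2^2 + k[5] * r2^3
  xd <- x * radial + 2 * k[3] * x * y + k[4] * (r2 + 2 * x^2)
  yd <- y * radial + k[3] * (r2 + 2 * y^2) + 2 * k[4] * x * y
  cbind(xd, yd, deparse.level = 0)
}

#' Project 3-D points into the image
#'
#' Homogeneous pinhole projection: points are carried into the camera frame
#' by `extr`, divided by depth, distorted in normalized coordinates, and
#' mapped through the intrinsic matrix.  The projective scale (camera-frame
#' depth) is consumed internally; projections are therefore invariant to the
#' depth of a point along its viewing ray.
#'
#' @param intr `camera_intrinsics`.
#' @param extr `rigid_transform` from the cloud's frame into the camera
#'   frame (the extrinsic matrix).
#' @param cloud `point_cloud` in `extr$frame_from`, or a bare N x 3 matrix.
#' @return M x 2 matrix of pixel coordinates `(u, v)`.
#' @export
project_points <- function(intr, extr, cloud) {
  stopifnot(inherits(intr, "camera_intrinsics"),
            inherits(extr, "rigid_transform"))
  if (inherits(cloud, "point_cloud")) {
    if (!identical(cloud$frame, extr$frame_from))
      stop(sprintf("project_points: cloud in frame '%s', extrinsics expect '%s'",
                   cloud$frame, extr$frame_from))
    pts <- cloud$points
  } else pts <- as.matrix(cloud)
  pc <- apply_transform(extr, pts)
  bad <- which(pc[, 3] <= 0)
  if (length(bad))
    stop(sprintf("project_points: point(s) %s at non-positive depth",
                 paste(head(bad, 5), collapse = ", ")))
  xy <- pc[, 1:2, drop = FALSE] / pc[, 3]
  xyd <- distort_normalized(intr, xy)
  cbind(intr$fx * xyd[, 1] + intr$cx, intr$fy * xyd[, 2] + intr$cy,
        deparse.level = 0)
}

#' Undistort pixel coordinates to normalized image coordinates
#'
#' Inverts the intrinsic map, then iteratively inverts the
#' radial-tangential distortion by fixed point: starting from the distorted
#' normalized coordinates, repeatedly divides out the radial factor and
#' subtracts the tangential term until the forward model reproduces the
#' input within `tol` (checked in pixels).
#'
#' @param intr `camera_intrinsics`.
#' @param pixels M x 2 pixel coordinates.
#' @param tol round-trip tolerance in px (default 1e-8).
#' @param max_iter fixed-point iteration cap (default 100).
#' @return M x 2 normalized (undistorted) image coordinates.
#' @export
undistort_pixels <- function(intr, pixels, tol = 1e-8, max_iter = 100) {
  pixels <- as.matrix(pixels)
  stopifnot(all(is.finite(pixels)), ncol(pixels) == 2)
  k <- intr$dist
  xd <- (pixels[, 1] - intr$cx) / intr$fx
  yd <- (pixels[, 2] - intr$cy) / intr$fy
  x <- xd; y <- yd
  for (i in seq_len(max_iter)) {
    r2 <- x^2 + y^2
    radial <- 1 + k[1] * r2 + k[2] * r2^2 + k[5] * r2^3
    dx <- 2 * k[3] * x * y + k[4] * (r2 + 2 * x^2)
    dy <- k[3] * (r2 + 2 * y^2) + 2 * k[4] * x * y
    xn <- (xd - dx) / radial
    yn <- (yd - dy) / radial
    shift <- max(abs(xn - x) * intr$fx, abs(yn - y) * intr$fy)
    x <- xn; y <- yn
    if (shift < tol) break
  }
  # verify round trip
  back <- distort_normalized(intr, cbind(x, y))
  err <- max(abs(back[, 1] - xd) * intr$fx, abs(back[, 2] - yd) * intr$fy)
  if (err > 1e-6)
    stop(sprintf("undistort_pixels: no convergence (residual %.3g px); distortion too extreme", err))
  cbind(x, y, deparse.level = 0)
}

#' Chessboard calibration observation
#'
#' One view of a planar chessboard: detected inner-corner pixel positions
#' together with the matching 3-D corner coordinates (board frame for
#' intrinsic calibration; tracker/marker frame for extrinsic estimation).
#'
#' @param corners_3d `point_cloud` of corner positions (mm).
#' @param corners_2d M x 2 pixel coordinates.
#' @param board_shape integer pair: inner corners per column and row.
#' @param square_size chessboard square edge length (mm).
#' @param planar_tol coplanarity tolerance for the 3-D corners (mm,
#'   default 1e-6; raise for stylus-probed boards).
#' @return An object of class `chessboard_observation`.
#' @export
chessboard_observation <- function(corners_3d, corners_2d, board_shape,
                                   square_size, planar_tol = 1e-6) {
  stopifnot(inherits(corners_3d, "point_cloud"))
  corners_2d <- as.matrix(corners_2d)
  m <- prod(board_shape)
  if (n_points(corners_3d) != m || nrow(corners_2d) != m)
    stop("chessboard_observation: corner count must equal prod(board_shape)")
  # coplanarity: smallest singular value of centred coordinates
  ctr <- sweep(corners_3d$points, 2, colMeans(corners_3d$points))
  s3 <- svd(ctr)$d[3]
  if (s3 > max(planar_tol, 1e-9 * max(abs(ctr))))
    stop(sprintf("chessboard_observation: corners not coplanar (residual %.3g mm)", s3))
  structure(list(corners_3d = corners_3d, corners_2d = corners_2d,
                 board_shape = as.integer(board_shape),
                 square_size = square_size),
            class = "chessboard_observation")
}

# Homography from planar 2-D correspondences (DLT with normalization).
estimate_homography <- function(src, dst) {
  norm_pts <- function(p) {
    c0 <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, c0)^2)))
    Tn <- rbind(c(sc, 0, -sc * c0[1]), c(0, sc, -sc * c0[2]), c(0, 0, 1))
    list(T = Tn, p = sweep(p, 2, c0) * sc)
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]
    u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  H / H[3, 3]
}

# Zhang closed-form intrinsics from a set of board->image homographies.
intrinsics_from_homographies <- function(Hs) {
  vrow <- function(H, i, j) {
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(Hs, function(H)
    rbind(vrow(H, 1, 2), vrow(H, 1, 1) - vrow(H, 2, 2))))
  b <- svd(V)$v[, 6]
  if (b[1] < 0) b <- -b  # overall sign of the conic is arbitrary
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  den <- B11 * B22 - B12^2
  v0 <- (B12 * B13 - B11 * B23) / den
  lam <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  if (lam / B11 <= 0 || lam * B11 / den <= 0)
    stop("calibrate_intrinsics: degenerate view geometry (closed-form failure)")
  alpha <- sqrt(lam / B11)
  beta <- sqrt(lam * B11 / den)
  gamma <- -B12 * alpha^2 * beta / lam
  u0 <- gamma * v0 / beta - B13 * alpha^2 / lam
  list(fx = alpha, fy = beta, cx = u0, cy = v0, skew = gamma)
}

# Extrinsics (board -> camera) from a homography given K.
extrinsics_from_homography <- function(H, K) {
  A <- solve(K) %*% H
  l1 <- 1 / sqrt(sum(A[, 1]^2))
  l2 <- 1 / sqrt(sum(A[, 2]^2))
  l <- (l1 + l2) / 2
  r1 <- A[, 1] * l1; r2 <- A[, 2] * l2
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  R <- orthonormalize(cbind(r1, r2, r3), max_drift = 1)
  t <- A[, 3] * l
  if (t[3] < 0) { R <- R %*% diag(c(-1, -1, 1)); t <- -t }
  list(R = R, t = t)
}

#' Zhang-style intrinsic calibration from chessboard views
#'
#' Per-view homographies give closed-form initial intrinsics via the
#' absolute-conic constraints; all parameters (fx, fy, cx, cy, the
#' distortion coefficients, and the per-view poses) are then refined
#' jointly by Levenberg-Marquardt on the total reprojection error.  Skew is
#' fixed at zero and k3 is excluded from refinement by default (it stays 0),
#' matching the common practice for narrow-field sensors.
#'
#' @param observations list of at least three [chessboard_observation()]s
#'   whose `corners_3d` are in the board frame (Z constant).
#' @param estimate_k3 include the sixth-order radial term (default FALSE).
#' @param width,height sensor size bound to the returned intrinsics
#'   (default 176 x 144).
#' @return A `camera_intrinsics` with attributes `rms_px` (final
#'   reprojection RMSE) and `poses` (list of refined board->camera
#'   `rigid_transform`s).
#' @export
calibrate_intrinsics <- function(observations, estimate_k3 = FALSE,
                                 width = 176, height = 144) {
  stopifnot(is.list(observations))
  if (length(observations) < 3)
    stop("calibrate_intrinsics: need at least 3 views")
  obs <- observations
  wh <- c(width, height)
  # board-plane coordinates: drop the (constant) normal component
  planes <- lapply(obs, function(o) {
    p <- o$corners_3d$points
    ctr <- sweep(p, 2, colMeans(p))
    sv <- svd(ctr)
    xy <- ctr %*% sv$v[, 1:2]
    list(xy = xy, uv = o$corners_2d)
  })
  Hs <- lapply(planes, function(pl) estimate_homography(pl$xy, pl$uv))
  ih <- intrinsics_from_homographies(Hs)
  if (ih$fx <= 0 || ih$fy <= 0)
    stop("calibrate_intrinsics: closed-form solution invalid")
  K <- rbind(c(ih$fx, 0, ih$cx), c(0, ih$fy, ih$cy), c(0, 0, 1))
  poses <- lapply(Hs, extrinsics_from_homography, K = K)

  ndist <- if (estimate_k3) 5L else 4L
  pack <- function(intr4, dist, poses) {
    c(intr4, dist[seq_len(ndist)],
      unlist(lapply(poses, function(p) c(matrix_to_rodrigues(p$R), p$t))))
  }
  nview <- length(obs)
  resid_fn <- function(par) {
    fx <- par[1]; fy <- par[2]; cx <- par[3]; cy <- par[4]
    dist <- c(par[5:(4 + ndist)], rep(0, 5 - ndist))
    if (fx <= 0 || fy <= 0) return(rep(1e6, 2 * sum(sapply(planes, function(p) nrow(p$uv)))))
    intr <- list(fx = fx, fy = fy, cx = cx, cy = cy, dist = dist)
    class(intr) <- "camera_intrinsics"
    res <- numeric(0)
    for (i in seq_len(nview)) {
      off <- 4 + ndist + 6 * (i - 1)
      R <- rodrigues_to_matrix(par[off + (1:3)])
      t <- par[off + (4:6)]
      p3 <- cbind(planes[[i]]$xy, 0)
      pc <- p3 %*% t(R) + rep(1, nrow(p3)) %o% t
      if (any(pc[, 3] <= 0)) return(rep(1e6, 2 * sum(sapply(planes, function(p) nrow(p$uv)))))
      xy <- pc[, 1:2, drop = FALSE] / pc[, 3]
      xyd <- distort_normalized(intr, xy)
      uv <- cbind(fx * xyd[, 1] + cx, fy * xyd[, 2] + cy)
      res <- c(res, as.numeric(uv - planes[[i]]$uv))
    }
    res
  }
  par0 <- pack(c(ih$fx, ih$fy, ih$cx, ih$cy), rep(0, 5), poses)
  fit <- minpack.lm::nls.lm(par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  par <- fit$par
  rms <- sqrt(mean(fit$fvec^2))
  dist <- c(par[5:(4 + ndist)], rep(0, 5 - ndist))
  out <- camera_intrinsics(par[1], par[2], par[3], par[4], dist,
                           width = wh[1], height = wh[2])
  attr(out, "rms_px") <- rms
  attr(out, "poses") <- lapply(seq_len(nview), function(i) {
    off <- 4 + ndist + 6 * (i - 1)
    rigid_transform(rodrigues_to_matrix(par[off + (1:3)]), par[off + (4:6)],
                    "board", "C")
  })
  out
}

#' Pose from 3-D/2-D correspondences (Perspective-n-Point)
#'
#' Estimates the rigid transform carrying world points into the camera frame
#' given known intrinsics.  Initialization is by DLT on the 3x4 projection
#' matrix for general configurations, or by homography decomposition when
#' the points are coplanar (the chessboard case); the pose is then refined
#' by Levenberg-Marquardt on the reprojection error, iterating until the
#' relative RMSE change falls below 1e-10 or 100 iterations.
#'
#' @param intr `camera_intrinsics`.
#' @param corners_3d `point_cloud` of at least 6 non-collinear world points.
#' @param corners_2d M x 2 matching pixel coordinates.
#' @return A `rigid_transform` from `corners_3d$frame` to `"C"`, with
#'   attribute `rms_px` (mean reprojection RMSE in px).
#' @export
solve_pnp <- function(intr, corners_3d, corners_2d) {
  stopifnot(inherits(intr, "camera_intrinsics"),
            inherits(corners_3d, "point_cloud"))
  P3 <- corners_3d$points
  uv <- as.matrix(corners_2d)
  m <- nrow(P3)
  if (m < 6) stop("solve_pnp: need at least 6 correspondences")
  ctr <- sweep(P3, 2, colMeans(P3))
  sv <- svd(ctr)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("solve_pnp: collinear (degenerate) point configuration")
  planar <- sv$d[3] < 1e-6 * sv$d[1]
  # work in undistorted normalized coordinates for initialization
  xyn <- undistort_pixels(intr, uv)
  if (planar) {
    xy <- ctr %*% sv$v[, 1:2]
    H <- estimate_homography(xy, xyn)
    ex <- extrinsics_from_homography(H, diag(3))
    # lift plane coords back to world: world = centroid + V[,1:2] %*% xy
    Rw <- ex$R %*% rbind(t(sv$v[, 1]), t(sv$v[, 2]),
                         t(c(sv$v[2, 1] * sv$v[3, 2] - sv$v[3, 1] * sv$v[2, 2],
                             sv$v[3, 1] * sv$v[1, 2] - sv$v[1, 1] * sv$v[3, 2],
                             sv$v[1, 1] * sv$v[2, 2] - sv$v[2, 1] * sv$v[1, 2])))
    R0 <- orthonormalize(Rw, max_drift = 1)
    t0 <- ex$t - as.numeric(R0 %*% colMeans(P3))
  } else {
    # DLT for the full 3x4 projection (normalized coordinates, K = I)
    A <- matrix(0, 2 * m, 12)
    for (i in seq_len(m)) {
      X <- c(P3[i, ], 1)
      A[2 * i - 1, ] <- c(X, rep(0, 4), -xyn[i, 1] * X)
      A[2 * i, ] <- c(rep(0, 4), X, -xyn[i, 2] * X)
    }
    p <- svd(A)$v[, 12]
    P <- matrix(p, 3, 4, byrow = TRUE)
    Rt <- P[, 1:3]
    sc <- (sqrt(sum(Rt[1, ]^2)) + sqrt(sum(Rt[2, ]^2)) + sqrt(sum(Rt[3, ]^2))) / 3
    P <- P / sc
    if (det(P[, 1:3]) < 0) P <- -P
    R0 <- orthonormalize(P[, 1:3], max_drift = 3)
    t0 <- P[, 4]
  }
  # LM refinement on pixel reprojection error, distortion included
  resid_fn <- function(par) {
    R <- rodrigues_to_matrix(par[1:3])
    t <- par[4:6]
    pc <- P3 %*% t(R) + rep(1, m) %o% t
    if (any(pc[, 3] <= 0)) return(rep(1e6, 2 * m))
    xy <- pc[, 1:2, drop = FALSE] / pc[, 3]
    xyd <- distort_normalized(intr, xy)
    as.numeric(cbind(intr$fx * xyd[, 1] + intr$cx,
                     intr$fy * xyd[, 2] + intr$cy) - uv)
  }
  fit <- minpack.lm::nls.lm(c(matrix_to_rodrigues(R0), t0), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-10, ptol = 1e-12))
  out <- rigid_transform(rodrigues_to_matrix(fit$par[1:3]), fit$par[4:6],
                         corners_3d$frame, "C")
  attr(out, "rms_px") <- sqrt(mean(fit$fvec^2))
  out
}

#' Projection-error report for calibration validation
#'
#' Projects tracker-measured test points through a solved calibration and
#' compares them with their detected pixel positions: the validation
#' protocol for a depth-camera/tracker rig.  Points that fall behind the
#' camera are excluded from the statistics and reported in `excluded`
#' rather than silently dropped.
#'
#' @param intr `camera_intrinsics`.
#' @param extr `rigid_transform` from the test-point frame into `"C"` (the
#'   extrinsics, possibly composed with a current tracker pose).
#' @param test_points `point_cloud` in `extr$frame_from`.
#' @param detections M x 2 detected pixel coordinates.
#' @return A `projection_report`: `per_point_error` (px, NA for excluded
#'   points), `mean_error`, `std_error`, and `excluded` indices.
#' @export
validate_projection <- function(intr, extr, test_points, detections) {
  stopifnot(inherits(test_points, "point_cloud"))
  detections <- as.matrix(detections)
  stopifnot(nrow(detections) == n_points(test_points))
  pc <- apply_transform(extr, test_points$points)
  ok <- pc[, 3] > 0
  err <- rep(NA_real_, nrow(pc))
  if (any(ok)) {
    keep_cloud <- point_cloud(test_points$points[ok, , drop = FALSE],
                              frame = test_points$frame)
    uv <- project_points(intr, extr, keep_cloud)
    err[ok] <- sqrt(rowSums((uv - detections[ok, , drop = FALSE])^2))
  }
  if (!any(ok)) stop("validate_projection: all points behind the camera")
  structure(list(per_point_error = err,
                 mean_error = mean(err[ok]),
                 std_error = if (sum(ok) > 1) sd(err[ok]) else 0,
                 excluded = which(!ok)),
            class = "projection_report")
}

#' @export
print.projection_report <- function(x, ...) {
  cat(sprintf("<projection_report: %.3f +/- %.3f px over %d points%s>\n",
              x$mean_error, x$std_error,
              sum(!is.na(x$per_point_error)),
              if (length(x$excluded))
                sprintf(" (%d excluded behind camera)", length(x$excluded))
              else ""))
  invisible(x)
}
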