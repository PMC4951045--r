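#' Rigid transform between two named coordinate frames
#'
#' A rigid transform maps points expressed in `frame_from` into `frame_to`
#' as `p' = R p + t`.  All translations are in millimetres, the native unit
#' of optical-tracker output; unit conversion is the caller's responsibility.
#' Frames are free-form string labels; the conventional ones in this package
#' are `"G"` (tracker global), `"C"` (depth camera), `"Z"` (marker fixed on
#' the camera) and `"CT"` (scanner/volume frame).  Frame checking is strict:
#' silent frame confusion is the classic failure mode of multi-sensor rigs,
#' so every operation verifies labels and errors on mismatch.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.  Validated on
#'   construction to within 1e-9; use [orthonormalize()] to repair drifted
#'   rotations before construction.
#' @param translation numeric length-3 vector (mm).
#' @param frame_from,frame_to frame labels (single strings).
#' @return An object of class `rigid_transform`.
#' @examples
#' T <- rigid_transform(diag(3), c(0, 0, 100), "C", "Z")
#' invert_transform(T)
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0),
                            frame_from = "A", frame_to = "B") {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite entries")
  ortho_err <- max(abs(crossprod(rotation) - diag(3)))
  det_err <- abs(det(rotation) - 1)
  if (ortho_err > 1e-9 || det_err > 1e-9)
    stop(sprintf(paste0("rigid_transform: rotation not orthonormal ",
                        "(|R'R-I|=%.3g, |det-1|=%.3g); see orthonormalize()"),
                 ortho_err, det_err))
  structure(list(rotation = rotation, translation = translation,
                 frame_from = as.character(frame_from)[1],
                 frame_to = as.character(frame_to)[1]),
            class = "rigid_transform")
}

#' Identity transform on a frame
#' @param frame frame label the identity acts on (both ends).
#' @return A `rigid_transform` with `R = I`, `t = 0`.
#' @export
rt_identity <- function(frame = "G") {
  rigid_transform(diag(3), c(0, 0, 0), frame, frame)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform %s -> %s>\n", x$frame_from, x$frame_to))
  m <- as_matrix(x)
  print(round(m, 6))
  invisible(x)
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param x a `rigid_transform`.
#' @return 4x4 matrix `[R t; 0 0 0 1]`.
#' @export
as_matrix <- function(x) UseMethod("as_matrix")

#' @export
as_matrix.rigid_transform <- function(x) {
  rbind(cbind(x$rotation, x$translation), c(0, 0, 0, 1))
}

#' Invert a rigid transform
#'
#' Returns the transform mapping `frame_to` back to `frame_from`:
#' `(R, t) -> (R', -R' t)` with frame labels swapped.
#' @param T a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  Rt <- t(T$rotation)
  rigid_transform(Rt, -Rt %*% T$translation, T$frame_to, T$frame_from)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(T2, T1)` is the map "first `T1`, then `T2`"; the
#' inner frame must match (`T1$frame_to == T2$frame_from`).  This is the
#' chain used to carry camera-frame points into the tracker global frame:
#' compose the time-indexed marker pose Z->G with the calibration C->Z.
#'
#' @param T2,T1 `rigid_transform` objects with `T1$frame_to == T2$frame_from`.
#' @return A `rigid_transform` mapping `T1$frame_from -> T2$frame_to`.
#' @export
compose_transforms <- function(T2, T1) {
  stopifnot(inherits(T2, "rigid_transform"), inherits(T1, "rigid_transform"))
  if (!identical(T1$frame_to, T2$frame_from))
    stop(sprintf("compose_transforms: frame mismatch ('%s' -> '%s' then '%s' -> '%s')",
                 T1$frame_from, T1$frame_to, T2$frame_from, T2$frame_to))
  R <- T2$rotation %*% T1$rotation
  # re-orthonormalize silently-accumulated drift below construction tolerance
  rigid_transform(orthonormalize(R),
                  as.numeric(T2$rotation %*% T1$translation + T2$translation),
                  T1$frame_from, T2$frame_to)
}

#' Nearest rotation matrix (polar decomposition)
#'
#' Projects a nearly-orthonormal 3x3 matrix onto the closest rotation in the
#' Frobenius norm via SVD (`R = U V'` with a sign correction so det = +1).
#' Intended as the explicit repair path for rotations that drifted through
#' accumulated floating-point error; matrices further than `max_drift` from
#' a rotation, or with non-positive determinant, indicate corrupt input and
#' raise an error instead of being silently repaired.
#'
#' @param M 3x3 matrix close to a rotation.
#' @param max_drift maximum allowed `max|M'M - I|` before erroring (default
#'   1e-3).
#' @return The nearest 3x3 rotation matrix.
#' @export
orthonormalize <- function(M, max_drift = 1e-3) {
  M <- as.matrix(M)
  stopifnot(identical(dim(M), c(3L, 3L)))
  if (det(M) <= 0)
    stop("orthonormalize: determinant <= 0 (reflection or degenerate matrix)")
  if (max(abs(crossprod(M) - diag(3))) > max_drift)
    stop("orthonormalize: matrix too far from a rotation (corrupt calibration?)")
  s <- svd(M)
  d <- det(s$u %*% t(s$v))
  s$u %*% diag(c(1, 1, sign(d))) %*% t(s$v)
}

#' Point cloud in a named frame
#'
#' @param points N x 3 numeric matrix of coordinates (mm).
#' @param frame frame label.
#' @param amplitude optional length-N vector of sensor amplitudes (a.u.).
#' @param confidence optional length-N vector of per-point confidence in
#'   \[0, 1\].
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, frame = "G", amplitude = NULL,
                        confidence = NULL) {
  points <- as.matrix(points)
  if (is.null(dim(points)) || ncol(points) != 3)
    stop("point_cloud: points must be an N x 3 matrix")
  if (nrow(points) < 1) stop("point_cloud: need at least one point")
  if (!all(is.finite(points))) stop("point_cloud: non-finite coordinates")
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (!is.null(amplitude)) {
    amplitude <- as.numeric(amplitude)
    stopifnot(length(amplitude) == nrow(points))
  }
  if (!is.null(confidence)) {
    confidence <- as.numeric(confidence)
    stopifnot(length(confidence) == nrow(points),
              all(confidence >= 0 & confidence <= 1))
  }
  structure(list(points = points, frame = as.character(frame)[1],
                 amplitude = amplitude, confidence = confidence),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points, frame '%s'%s%s>\n",
              nrow(x$points), x$frame,
              if (!is.null(x$amplitude)) ", amplitude" else "",
              if (!is.null(x$confidence)) ", confidence" else ""))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return Integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Apply a rigid transform to a point cloud
#'
#' Each point maps as `p -> R p + t`; amplitude and confidence channels are
#' carried through untouched.  The cloud must be expressed in the transform's
#' source frame.
#'
#' @param T a `rigid_transform`.
#' @param cloud a `point_cloud` with `cloud$frame == T$frame_from`, or a bare
#'   N x 3 matrix (no frame check).
#' @return The transformed cloud (or matrix), in `T$frame_to`.
#' @export
apply_transform <- function(T, cloud) {
  stopifnot(inherits(T, "rigid_transform"))
  if (is.matrix(cloud) || is.numeric(cloud)) {
    p <- if (is.matrix(cloud)) cloud else matrix(cloud, ncol = 3)
    return(p %*% t(T$rotation) + rep(1, nrow(p)) %o% T$translation)
  }
  stopifnot(inherits(cloud, "point_cloud"))
  if (!identical(cloud$frame, T$frame_from))
    stop(sprintf("apply_transform: cloud in frame '%s' but transform expects '%s'",
                 cloud$frame, T$frame_from))
  pts <- cloud$points %*% t(T$rotation) + rep(1, nrow(cloud$points)) %o% T$translation
  point_cloud(pts, T$frame_to, cloud$amplitude, cloud$confidence)
}

#' Marker pose observed by the tracker at a time point
#'
#' @param transform `rigid_transform` mapping the marker frame into the
#'   tracker's global frame.
#' @param timestamp acquisition time (seconds).
#' @return An object of class `tracked_pose`.
#' @export
tracked_pose <- function(transform, timestamp = 0) {
  stopifnot(inherits(transform, "rigid_transform"), is.finite(timestamp))
  structure(list(transform = transform, timestamp = as.numeric(timestamp)),
            class = "tracked_pose")
}

# -- internal rotation helpers -------------------------------------------------

# Rotation about a unit axis by angle (radians), Rodrigues form.
rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Rotation-vector (axis*angle) to matrix and back; used by camera refinement.
rodrigues_to_matrix <- function(rvec) {
  th <- sqrt(sum(rvec^2))
  if (th < 1e-12) return(diag(3))
  rotation_about(rvec / th, th)
}

matrix_to_rodrigues <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  ca <- min(1, max(-1, ca))
  th <- acos(ca)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near-pi: extract axis from R + I
    A <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(A), 0))
    # fix signs from off-diagonals
    i <- which.max(axis)
    s <- sign(A[i, ])
    s[s == 0] <- 1
    axis <- axis * s * sign(axis[i])
    axis <- axis / sqrt(sum(axis^2))
    return(axis * th)
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th))
  axis * th
}

# Angle (radians) of the relative rotation between two rotation matrices.
rotation_angle_between <- function(R1, R2) {
  ca <- (sum(diag(t(R1) %*% R2)) - 1) / 2
  acos(min(1, max(-1, ca)))
}

# Uniformly random rotation (used by the simulator and tests).
random_rotation <- function() {
  # QR of a Gaussian matrix with sign fix gives Haar-distributed rotations
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
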