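# Independent oracles and small generators shared across tests.
# These deliberately use naive O(N*M) scans and hand-written loops so they
# share no code path with the package implementations they check.

# Brute-force nearest neighbour: first-wins index per probe row.
bf_nearest <- function(probes, target) {
  idx <- integer(nrow(probes))
  dst <- numeric(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    d2 <- colSums((t(target) - probes[i, ])^2)
    idx[i] <- which.min(d2)
    dst[i] <- sqrt(d2[idx[i]])
  }
  list(index = idx, distance = dst)
}

# All pairwise distances of a point matrix.
bf_pairwise <- function(p) as.matrix(stats::dist(p))

# Random proper rotation (independent of the package helper).
rand_rot <- function() {
  th <- runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1])), 3, 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0, sin(th[2]), 0, cos(th[2])), 3, 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Rotation by a bounded angle about a random axis.
rand_rot_bounded <- function(max_angle) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, max_angle)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

rot_angle <- function(R1, R2 = diag(3)) {
  ca <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(min(1, max(-1, ca)))
}

# Plain unweighted fuzzy c-means from given initial centres (oracle for the
# weighted implementation at equal weights).
bf_fcm <- function(X, centers, m = 2, tol = 1e-6, max_iter = 300) {
  k <- nrow(centers)
  n <- nrow(X)
  C <- centers
  for (it in seq_len(max_iter)) {
    D2 <- matrix(0, n, k)
    for (j in seq_len(k)) D2[, j] <- colSums((t(X) - C[j, ])^2)
    U <- matrix(0, n, k)
    for (i in seq_len(n)) {
      if (any(D2[i, ] < 1e-300)) {
        U[i, which.min(D2[i, ])] <- 1
      } else {
        p <- D2[i, ]^(-1 / (m - 1))
        U[i, ] <- p / sum(p)
      }
    }
    Cn <- C
    for (j in seq_len(k)) {
      wj <- U[, j]^m
      Cn[j, ] <- colSums(X * wj) / sum(wj)
    }
    if (max(abs(Cn - C)) < tol) { C <- Cn; break }
    C <- Cn
  }
  C
}

# 3x4-matrix pinhole projection oracle (no distortion).
bf_project <- function(fx, fy, cx, cy, R, t, pts) {
  K <- rbind(c(fx, 0, cx), c(0, fy, cy), c(0, 0, 1))
  P <- K %*% cbind(R, t)
  X <- t(cbind(pts, 1))
  h <- P %*% X
  cbind(h[1, ] / h[3, ], h[2, ] / h[3, ])
}

# Small cloud sampled from a phantom surface (structured, non-symmetric).
phantom_cloud <- function(n = 800, seed = 1, frame = "S") {
  mesh <- make_phantom("femur_like", seed = seed)
  v <- mesh$vertices
  idx <- with(list(), {set.seed(seed + 99); sample.int(nrow(v), min(n, nrow(v)))})
  point_cloud(v[idx, , drop = FALSE], frame = frame)
}
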