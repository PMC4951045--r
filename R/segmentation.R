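# Surface extraction from CT-like volumes and object segmentation of ToF
# depth frames.

#' CT-like scalar volume
#'
#' @param data 3-D numeric array of voxel values (Hounsfield units; air is
#'   about -1000 HU, water 0 HU).
#' @param spacing length-3 voxel spacing (mm), all positive.
#' @param origin world position (mm) of the centre of voxel `[1, 1, 1]`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  if (!all(is.finite(data))) stop("ct_volume: non-finite voxel values")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume %s, spacing %s mm, range [%.0f, %.0f] HU>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' ToF depth frame
#'
#' Per-pixel 3-D coordinates (camera frame, mm), amplitude and confidence,
#' as delivered by a time-of-flight sensor.  Arrays are indexed
#' `[row = v + 1, col = u + 1]`.
#'
#' @param xyz H x W x 3 array of camera-frame coordinates (mm).
#' @param amplitude H x W amplitude (intensity) image, arbitrary units.
#' @param confidence H x W per-pixel confidence in \[0, 1\].
#' @param valid optional H x W logical mask of usable pixels (default all).
#' @return An object of class `depth_frame`.
#' @export
depth_frame <- function(xyz, amplitude, confidence, valid = NULL) {
  stopifnot(is.array(xyz), length(dim(xyz)) == 3, dim(xyz)[3] == 3)
  hw <- dim(xyz)[1:2]
  stopifnot(identical(dim(amplitude), hw), identical(dim(confidence), hw))
  if (is.null(valid)) valid <- array(TRUE, hw)
  stopifnot(identical(dim(valid), hw))
  cv <- confidence[valid]
  if (any(!is.finite(cv)) || any(cv < 0 | cv > 1))
    stop("depth_frame: confidence must lie in [0, 1] on valid pixels")
  structure(list(xyz = xyz, amplitude = amplitude, confidence = confidence,
                 valid = valid),
            class = "depth_frame")
}

#' @export
print.depth_frame <- function(x, ...) {
  cat(sprintf("<depth_frame %dx%d, %d valid pixels>\n",
              dim(x$amplitude)[2], dim(x$amplitude)[1], sum(x$valid)))
  invisible(x)
}

#' Otsu threshold of a volume's intensity histogram
#'
#' Maximizes the between-class variance over a 256-bin histogram spanning
#' the data range.  When several bin boundaries tie for the maximum (the
#' usual case for well-separated classes, whose histogram has an empty gap),
#' the midpoint of the tying plateau is returned -- the canonical handling
#' in classic implementations of the method.
#'
#' @param x a `ct_volume` or numeric vector/array.
#' @param nbins histogram bin count (default 256).
#' @return Threshold on the input intensity scale (HU for CT volumes).
#' @export
otsu_threshold <- function(x, nbins = 256) {
  v <- if (inherits(x, "ct_volume")) as.numeric(x$data) else as.numeric(x)
  rng <- range(v)
  if (rng[1] == rng[2]) stop("otsu_threshold: constant input")
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins)
  mids <- (br[-1] + br[-(nbins + 1)]) / 2
  w <- cnt / sum(cnt)
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[nbins]
  sb <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  sb <- sb[-nbins]  # threshold after bin i splits classes 1..i | i+1..n
  mx <- max(sb)
  plateau <- which(sb >= mx - 1e-12 * max(abs(mx), 1))
  i <- mean(plateau)
  br[1] + i * (br[2] - br[1])
}

#' Extract the outer object surface from a CT-like volume
#'
#' Pipeline: Otsu threshold (foreground = above threshold) -> binary closing
#' with a ball structuring element -> largest 26-connected component ->
#' per-slice hole filling -> vertices of the 0.5-level isosurface of the
#' binary mask (every grid-edge crossing between a foreground and a
#' background voxel, i.e. the marching-cubes vertex set), scaled by the
#' voxel spacing and offset by the volume origin.
#'
#' @param volume a `ct_volume`.
#' @param threshold override the automatic Otsu threshold (HU).
#' @param close_radius closing ball radius in voxels (default 2, enough to
#'   bridge typical surface pitting without merging nearby structures).
#' @param frame frame label of the returned surface (default `"CT"`).
#' @return A `point_cloud` of surface vertices (mm) with attribute `mask`
#'   (the final binary array) and `threshold`.
#' @export
segment_ct <- function(volume, threshold = NULL, close_radius = 2,
                       frame = "CT") {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(threshold)) threshold <- otsu_threshold(volume)
  dims <- dim(volume$data)
  mask <- as.logical(volume$data > threshold)
  if (!any(mask)) stop("segment_ct: empty foreground after thresholding")
  mask <- .binary_close(mask, dims, close_radius)
  mask <- .largest_component26(mask, dims)
  mask <- .fill_holes_slices(mask, dims)
  vox <- .isosurface_points(mask, dims)  # 0-based continuous voxel coords
  if (nrow(vox) == 0) stop("segment_ct: empty surface")
  pts <- sweep(sweep(vox, 2, volume$spacing, `*`), 2, volume$origin, `+`)
  out <- point_cloud(pts, frame = frame)
  attr(out, "mask") <- array(mask, dims)
  attr(out, "threshold") <- threshold
  out
}

#' Weighted fuzzy c-means clustering
#'
#' Alternating optimization of the weighted fuzzy c-means objective
#' `sum_i sum_j w_i u_ij^m ||x_i - c_j||^2`: membership update
#' `u_ij proportional to d_ij^(-2/(m-1))` normalized over clusters, centre
#' update as the weight-and-membership weighted mean.  The objective is
#' non-increasing across iterations (checked at each step).  Centres are
#' initialized by a weighted k-means++ scheme, so results are deterministic
#' given `seed`.  A cluster whose total weighted membership collapses is
#' re-seeded from the highest-weight point farthest from the surviving
#' centres; repeated collapse raises an error.
#'
#' @param features N x d numeric matrix.
#' @param weights length-N non-negative point weights (default all 1).
#' @param k number of clusters (>= 2).
#' @param m fuzzifier (> 1; default 2).
#' @param seed integer seed for centre initialization.
#' @param tol convergence threshold on the maximum centre shift
#'   (default 1e-6).
#' @param max_iter iteration cap (default 300).
#' @return A `labelling`: `labels` (argmax memberships), `memberships`
#'   (N x k, rows sum to 1), `centers` (k x d), `objective` (per-iteration
#'   values), `iterations`.
#' @export
wfcm <- function(features, weights = NULL, k = 2, m = 2, seed = 1,
                 tol = 1e-6, max_iter = 300) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  w <- as.numeric(weights)
  stopifnot(k >= 2, n > k, m > 1, length(w) == n, all(w >= 0))
  if (all(w == 0)) stop("wfcm: all weights are zero")

  dist2 <- function(C) {
    # n x k squared distances
    outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
      outer(rep(1, n), rowSums(C^2))
  }
  # weighted k-means++ initialization (caller's RNG state is preserved)
  C <- local({
    if (exists(".Random.seed", envir = globalenv())) {
      saved <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", saved, envir = globalenv()))
    }
    set.seed(seed)
    idx <- sample.int(n, 1, prob = w / sum(w))
    centers <- X[idx, , drop = FALSE]
    for (j in 2:k) {
      d2 <- pmax(apply(dist2(centers), 1, min), 0)
      p <- w * d2
      if (sum(p) <= 0) p <- w
      centers <- rbind(centers, X[sample.int(n, 1, prob = p / sum(p)), ])
    }
    centers
  })

  C0 <- C
  obj <- numeric(0)
  reseeds <- 0
  U <- NULL
  for (it in seq_len(max_iter)) {
    D2 <- pmax(dist2(C), 0)
    # membership update; points coincident with a centre get crisp membership
    U <- matrix(0, n, k)
    zero <- D2 < 1e-300
    hasz <- rowSums(zero) > 0
    if (any(hasz))
      U[hasz, ] <- zero[hasz, , drop = FALSE] /
        rowSums(zero[hasz, , drop = FALSE])
    if (any(!hasz)) {
      P <- D2[!hasz, , drop = FALSE]^(-1 / (m - 1))
      U[!hasz, ] <- P / rowSums(P)
    }
    J <- sum(w * rowSums(U^m * D2))
    if (length(obj) && J > obj[length(obj)] * (1 + 1e-9) + 1e-12)
      stop("wfcm: objective increased (internal error)")
    obj <- c(obj, J)
    Wm <- w * U^m
    mass <- colSums(Wm)
    dead <- which(mass <= 1e-12 * sum(w))
    if (length(dead)) {
      reseeds <- reseeds + length(dead)
      if (reseeds > 2 * k) stop("wfcm: repeated cluster collapse")
      dmin <- apply(dist2(C[-dead, , drop = FALSE]), 1, min)
      far <- which.max(w * dmin)
      C[dead, ] <- matrix(X[far, ], length(dead), ncol(X), byrow = TRUE)
      next
    }
    Cn <- sweep(crossprod(Wm, X), 1, mass, `/`)
    shift <- max(abs(Cn - C))
    C <- Cn
    if (shift < tol) break
  }
  structure(list(labels = max.col(U, ties.method = "first"),
                 memberships = U, centers = C, initial_centers = C0,
                 objective = obj, iterations = length(obj)),
            class = "labelling")
}

#' @export
print.labelling <- function(x, ...) {
  cat(sprintf("<labelling: %d points, %d clusters, %d iterations>\n",
              nrow(x$memberships), ncol(x$memberships), x$iterations))
  invisible(x)
}

#' Segment the object from a ToF depth frame
#'
#' Confidence-gated weighted fuzzy c-means segmentation: pixels below
#' `confidence_min` are discarded first (this suppresses flying pixels,
#' whose confidence is low by construction), then each remaining pixel is
#' described by the feature vector (standardized x, y, z, amplitude) and
#' clustered by [wfcm()] with the per-pixel confidence as weight.  The
#' object cluster is the one with the highest mean amplitude; if two
#' cluster amplitudes are within 5 % of each other, the nearer mean depth
#' wins the tie.
#'
#' @param frame a `depth_frame`.
#' @param confidence_min confidence gate in \[0, 1\] (default 0.3).
#' @param k cluster count (default 2: object vs background).
#' @param seed seed passed to [wfcm()].
#' @param amplitude_scale relative weight of the amplitude channel after
#'   standardization (default 1).
#' @return A `point_cloud` in frame `"C"` of the object pixels, amplitude
#'   and confidence attached, with attribute `pixel_index` (indices into
#'   the H x W grid) and `labelling`.
#' @export
segment_tof <- function(frame, confidence_min = 0.3, k = 2, seed = 1,
                        amplitude_scale = 1) {
  stopifnot(inherits(frame, "depth_frame"))
  sel <- which(frame$valid & frame$confidence >= confidence_min)
  if (!length(sel)) stop("segment_tof: no pixels above the confidence gate")
  hw <- dim(frame$amplitude)
  xyz <- matrix(frame$xyz, prod(hw), 3)[sel, , drop = FALSE]
  amp <- frame$amplitude[sel]
  conf <- frame$confidence[sel]
  std <- function(v) {
    s <- sd(v)
    (v - mean(v)) / if (s > 0) s else 1
  }
  feats <- cbind(std(xyz[, 1]), std(xyz[, 2]), std(xyz[, 3]),
                 amplitude_scale * std(amp))
  lab <- wfcm(feats, weights = conf, k = k, seed = seed)
  amp_mean <- tapply(amp, lab$labels, mean)
  depth_mean <- tapply(xyz[, 3], lab$labels, mean)
  cand <- as.integer(names(amp_mean))
  best_amp <- max(amp_mean)
  near <- cand[amp_mean >= 0.95 * best_amp]
  object <- near[which.min(depth_mean[as.character(near)])]
  pick <- lab$labels == object
  out <- point_cloud(xyz[pick, , drop = FALSE], frame = "C",
                     amplitude = amp[pick], confidence = conf[pick])
  attr(out, "pixel_index") <- sel[pick]
  attr(out, "labelling") <- lab
  out
}
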