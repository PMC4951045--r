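# Deterministic synthetic-scene generator: parametric phantoms, ray-cast
# ToF depth frames with flying pixels, stylus sweep clouds, CT voxelization
# and chessboard calibration views, all with exported ground truth.  The
# generator stands in for the physical rig (depth camera + optical tracker
# + CT scanner) so the whole pipeline can be validated against known poses.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    saved <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", saved, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# -- icosphere ---------------------------------------------------------------

# Unit icosphere by repeated 4-to-1 subdivision of an icosahedron.
# Watertight by construction (shared edges deduplicated via midpoint cache).
icosphere <- function(subdiv = 4) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(V)
    newV <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (V[a, ] + V[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      newV[[length(newV) + 1]] <<- m
      idx <- nv + length(newV)
      mid_cache[[key]] <- idx
      idx
    }
    newF <- matrix(0L, 4 * nrow(F), 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; cc <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF[4 * f - 3, ] <- c(a, ab, ca)
      newF[4 * f - 2, ] <- c(b, bc, ab)
      newF[4 * f - 1, ] <- c(cc, ca, bc)
      newF[4 * f, ] <- c(ab, bc, ca)
    }
    V <- rbind(V, do.call(rbind, newV))
    F <- newF
  }
  list(vertices = V, faces = F)
}

#' Parametric phantom mesh
#'
#' Closed, watertight triangle meshes mimicking the phantom classes used on
#' a registration rig: a bone-like elongated shape, a limb, a head, a
#' breast, and an exact sphere.  The non-sphere kinds are built as
#' superellipsoids radially perturbed by a seeded smooth bump field, so
#' they are deliberately non-symmetric (near-symmetric objects are the
#' known failure mode of ICP, which can lock onto a flipped pose).  Every
#' phantom is star-shaped about the origin; its radial function is attached
#' as attribute `radial` (a function of unit directions) and is used by the
#' stylus and CT generators for exact surface/inside tests.
#'
#' @param kind one of `"femur_like"`, `"limb_like"`, `"head_like"`,
#'   `"breast_like"`, `"sphere"`.
#' @param seed integer seed for the bump field.
#' @param subdiv icosphere subdivision level (default 4, 2562 vertices).
#' @param radius sphere radius in mm (sphere kind only, default 40).
#' @return A `surface_mesh`: list with `vertices` (mm), `faces` (1-based),
#'   attributes `radial`, `kind`, `seed`, and for the sphere kind
#'   `analytic = list(type = "sphere", radius)`.
#' @export
make_phantom <- function(kind = c("femur_like", "limb_like", "head_like",
                                  "breast_like", "sphere"),
                         seed = 1, subdiv = 4, radius = 40) {
  kind <- match.arg(kind)
  base <- icosphere(subdiv)
  if (kind == "sphere") {
    radial <- local({
      r <- radius
      function(U) rep(r, nrow(U))
    })
    mesh <- list(vertices = base$vertices * radius, faces = base$faces)
  } else {
    params <- switch(kind,
      femur_like = list(ax = c(95, 34, 26), p = 2.6, nb = 6, amp = 0.10),
      limb_like  = list(ax = c(115, 42, 34), p = 2.2, nb = 5, amp = 0.08),
      head_like  = list(ax = c(72, 58, 52), p = 2.0, nb = 5, amp = 0.07),
      breast_like = list(ax = c(62, 56, 36), p = 2.0, nb = 4, amp = 0.14))
    bumps <- with_seed(seed, {
      dirs <- matrix(rnorm(3 * params$nb), params$nb, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      list(dirs = dirs,
           amp = runif(params$nb, 0.3, 1) * params$amp,
           width = runif(params$nb, 0.35, 0.8))
    })
    radial <- local({
      ax <- params$ax; p <- params$p; b <- bumps
      function(U) {
        r0 <- (abs(U[, 1] / ax[1])^p + abs(U[, 2] / ax[2])^p +
                 abs(U[, 3] / ax[3])^p)^(-1 / p)
        mod <- rep(1, nrow(U))
        for (i in seq_len(nrow(b$dirs))) {
          ca <- pmin(1, pmax(-1, U %*% b$dirs[i, ]))
          ang <- acos(ca)
          mod <- mod + b$amp[i] * exp(-(ang / b$width[i])^2)
        }
        r0 * mod
      }
    })
    U <- base$vertices
    mesh <- list(vertices = U * as.numeric(radial(U)), faces = base$faces)
  }
  class(mesh) <- "surface_mesh"
  attr(mesh, "radial") <- radial
  attr(mesh, "kind") <- kind
  attr(mesh, "seed") <- seed
  if (kind == "sphere")
    attr(mesh, "analytic") <- list(type = "sphere", radius = radius)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh '%s': %d vertices, %d faces>\n",
              attr(x, "kind"), nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Face normals (unit), nf x 3.
mesh_face_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], ] - V[F[, 1], ]
  e2 <- V[F[, 3], ] - V[F[, 1], ]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

#' Simulate a ToF depth-frame acquisition
#'
#' Casts one ray per pixel through the pinhole model and intersects it with
#' the phantom (analytically for the sphere phantom, triangle-exact
#' otherwise) and with a background plane placed behind the phantom.
#' Gaussian depth noise is applied along the viewing ray (depth error
#' dominates lateral error on ToF sensors).  Pixels adjacent to the object
#' silhouette become "flying pixels": their range mixes foreground and
#' background and their confidence drops below 0.2.  Amplitude falls off
#' with squared range and incidence angle; confidence is high on the object
#' interior, moderate on the background, low at edges.
#'
#' @param mesh a `surface_mesh` (in its own frame).
#' @param intr `camera_intrinsics` (default ToF-like 176 x 144, f = 250 px).
#' @param pose `rigid_transform` from the mesh frame to `"C"`; default
#'   places the mesh centre 800 mm in front of the camera.
#' @param noise list: `sigma_z` depth noise SD in mm (default 5),
#'   `flying` logical (default TRUE), `background_offset` mm behind the
#'   phantom (default 300).
#' @param seed integer seed.
#' @return List: `frame` (a `depth_frame`), `truth` (list with `mask`
#'   H x W ground-truth object mask, `flying` H x W flags, `pose`, `intr`).
#' @export
simulate_tof <- function(mesh, intr = NULL, pose = NULL,
                         noise = list(), seed = 1) {
  if (is.null(intr)) intr <- camera_intrinsics(250, 250, 88, 72)
  nz <- list(sigma_z = 5, flying = TRUE, background_offset = 300)
  nz[names(noise)] <- noise
  if (is.null(pose))
    pose <- rigid_transform(diag(3), c(0, 0, 800), "phantom", "C")
  V <- apply_transform(pose, mesh$vertices)
  if (max(V[, 3]) <= 0) stop("simulate_tof: mesh behind the camera")
  H <- intr$height; W <- intr$width
  uv <- cbind(rep(0:(W - 1), each = H), rep(0:(H - 1), W))
  dirs <- cbind((uv[, 1] - intr$cx) / intr$fx,
                (uv[, 2] - intr$cy) / intr$fy, 1)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  analytic <- attr(mesh, "analytic")
  if (!is.null(analytic) && analytic$type == "sphere") {
    ctr <- as.numeric(apply_transform(pose, matrix(0, 1, 3)))
    r <- analytic$radius
    bq <- as.numeric(dirs %*% ctr)  # solve t^2 - 2t(d.c) + |c|^2 - r^2 = 0
    disc <- bq^2 - (sum(ctr^2) - r^2)
    t_obj <- ifelse(disc >= 0, bq - sqrt(pmax(disc, 0)), Inf)
    t_obj[t_obj < 0] <- Inf
    hit_normal <- (dirs * as.numeric(t_obj) -
                     rep(1, nrow(dirs)) %o% ctr) / r
    hit_normal[!is.finite(t_obj), ] <- NA
  } else {
    rc <- .raycast_mesh(V, mesh$faces, matrix(0, nrow(dirs), 3), dirs)
    t_obj <- rc$t
    fn <- mesh_face_normals(list(vertices = V, faces = mesh$faces))
    hit_normal <- matrix(NA_real_, nrow(dirs), 3)
    hv <- rc$face > 0
    hit_normal[hv, ] <- fn[rc$face[hv], ]
  }
  z_bg <- max(V[, 3]) + nz$background_offset
  t_bg <- z_bg / dirs[, 3]
  mask <- is.finite(t_obj)
  cosi <- abs(rowSums(hit_normal * dirs))
  cosi[!mask] <- abs(dirs[!mask, 3])  # background plane faces the camera

  # silhouette band: 3x3 neighbourhood contains both object and background
  M <- matrix(mask, H, W)
  grow <- function(A) {
    B <- A
    B[-1, ] <- B[-1, ] | A[-H, ]
    B[-H, ] <- B[-H, ] | A[-1, ]
    B[, -1] <- B[, -1] | A[, -W]
    B[, -W] <- B[, -W] | A[, 1:(W - 1)]
    B
  }
  dil <- grow(grow(M))  # 1-pixel 8-ish dilation via two 4-dilations
  ero <- !grow(grow(!M))
  band <- dil & !ero

  out <- with_seed(seed, {
    flying <- rep(FALSE, H * W)
    t_meas <- ifelse(mask, t_obj, t_bg)
    if (nz$flying && any(band)) {
      cand <- which(as.vector(band))
      flying[cand] <- runif(length(cand)) < 0.7
      if (any(flying)) {
        idx <- which(flying)
        # mix the local object range with the background range
        tnear <- t_meas[idx]
        miss <- !mask[idx]
        if (any(miss)) {
          # nearest object pixel in the same row neighbourhood
          obj_t <- t_meas
          obj_t[!mask] <- NA
          Mt <- matrix(obj_t, H, W)
          for (ii in idx[miss]) {
            r0 <- (ii - 1) %% H + 1; c0 <- (ii - 1) %/% H + 1
            rr <- max(1, r0 - 2):min(H, r0 + 2)
            cc <- max(1, c0 - 2):min(W, c0 + 2)
            loc <- Mt[rr, cc]
            tnear[match(ii, idx)] <-
              if (all(is.na(loc))) t_meas[ii] else min(loc, na.rm = TRUE)
          }
        }
        lam <- runif(length(idx), 0.2, 0.8)
        t_meas[idx] <- lam * tnear + (1 - lam) * t_bg[idx]
      }
    }
    t_meas <- t_meas + rnorm(H * W, 0, nz$sigma_z)
    refl <- ifelse(mask, 1.0, 0.3)
    amp <- refl * cosi / (ifelse(mask, t_obj, t_bg) / 1000)^2
    amp <- amp / max(amp)
    amp <- pmax(amp + rnorm(H * W, 0, 0.01), 0)
    conf <- ifelse(mask, pmin(0.7 + 0.29 * cosi, 0.99),
                   runif(H * W, 0.35, 0.7))
    conf[flying] <- runif(sum(flying), 0.05, 0.19)
    list(t = t_meas, amp = amp, conf = conf, flying = flying)
  })
  xyz <- array(dirs * out$t, c(H, W, 3))
  frame <- depth_frame(xyz,
                       amplitude = matrix(out$amp, H, W),
                       confidence = matrix(out$conf, H, W))
  list(frame = frame,
       truth = list(mask = M, flying = matrix(out$flying, H, W),
                    pose = pose, intr = intr))
}

#' Simulate a tracked-stylus surface acquisition
#'
#' Samples points along smooth sweep trajectories over the phantom surface
#' (meridian-style strokes with a seeded azimuthal wobble), mimicking an
#' operator sliding a tracked stylus across the object.  Only the
#' accessible part of the surface is covered: strokes stop at polar angle
#' `access_deg` measured from +z, leaving the resting base unsampled.
#' Isotropic Gaussian noise models tracked-tool error.
#'
#' @param mesh a `surface_mesh` with a `radial` attribute (any
#'   [make_phantom()] output).
#' @param n_points total number of samples (honoured exactly; default 2000).
#' @param noise_sigma isotropic noise SD in mm (default 0.25, tracked-tool
#'   class accuracy).
#' @param n_strokes number of sweep strokes (default 25).
#' @param access_deg maximum polar angle reached by the stylus, degrees
#'   from +z (default 135).
#' @param pose optional `rigid_transform` from the mesh frame to `"G"`;
#'   identity relabelling by default.
#' @param seed integer seed.
#' @return A `point_cloud` in frame `"G"`.
#' @export
simulate_stylus <- function(mesh, n_points = 2000, noise_sigma = 0.25,
                            n_strokes = 25, access_deg = 135, pose = NULL,
                            seed = 1) {
  radial <- attr(mesh, "radial")
  if (is.null(radial)) stop("simulate_stylus: mesh lacks a radial function")
  pts <- with_seed(seed, {
    per <- ceiling(n_points / n_strokes)
    phis <- seq(0, 2 * pi, length.out = n_strokes + 1)[seq_len(n_strokes)] +
      runif(n_strokes, 0, 2 * pi / n_strokes)
    wob_amp <- runif(n_strokes, 0.02, 0.12)
    wob_ph <- runif(n_strokes, 0, 2 * pi)
    th_max <- access_deg * pi / 180
    P <- list()
    for (s in seq_len(n_strokes)) {
      th <- seq(0.03, th_max, length.out = per)
      ph <- phis[s] + wob_amp[s] * sin(3 * th + wob_ph[s])
      U <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      P[[s]] <- U * as.numeric(radial(U))
    }
    P <- do.call(rbind, P)[seq_len(n_points), , drop = FALSE]
    P + matrix(rnorm(3 * n_points, 0, noise_sigma), n_points, 3)
  })
  cloud <- point_cloud(pts, frame = if (is.null(pose)) "G" else pose$frame_from)
  if (!is.null(pose)) cloud <- apply_transform(pose, cloud)
  if (!identical(cloud$frame, "G")) cloud$frame <- "G"
  cloud
}

#' Voxelize a phantom into a CT-like volume
#'
#' Inside/outside test per voxel centre (via the phantom's radial function,
#' or parity ray-casting for plain meshes), Hounsfield values drawn from
#' two Gaussian classes (object and air), then a 1-voxel Gaussian blur
#' modelling partial-volume averaging.
#'
#' @param mesh a `surface_mesh`.
#' @param spacing voxel spacing, mm (scalar or length-3; default 1).
#' @param hu_object mean and SD of the object class (default `c(50, 50)` HU,
#'   a solid phantom material just above water density).
#' @param hu_air mean and SD of the air class (default `c(-1000, 30)` HU).
#' @param pad padding around the mesh bounding box, mm (default 20).
#' @param blur_sigma partial-volume blur SD in voxels (default 1).
#' @param seed integer seed for the HU noise.
#' @return A `ct_volume` with attribute `inside` (the ground-truth binary
#'   mask).
#' @export
voxelize_ct <- function(mesh, spacing = 1, hu_object = c(50, 50),
                        hu_air = c(-1000, 30), pad = 20, blur_sigma = 1,
                        seed = 1) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  stopifnot(all(spacing > 0))
  V <- mesh$vertices
  lo <- apply(V, 2, min) - pad
  hi <- apply(V, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  origin <- lo
  radial <- attr(mesh, "radial")
  ax <- lapply(1:3, function(i) origin[i] + (seq_len(dims[i]) - 1) * spacing[i])
  if (!is.null(radial)) {
    P <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
    nrm <- sqrt(rowSums(P^2))
    U <- P / pmax(nrm, 1e-12)
    inside <- nrm <= radial(U)
  } else {
    inside <- .voxelize_mesh(V, mesh$faces, origin, spacing, dims)
  }
  hu <- with_seed(seed, {
    v <- rnorm(length(inside), hu_air[1], hu_air[2])
    v[inside] <- rnorm(sum(inside), hu_object[1], hu_object[2])
    v
  })
  if (blur_sigma > 0) hu <- .gaussian_blur3(hu, dims, blur_sigma)
  out <- ct_volume(array(hu, dims), spacing = spacing, origin = origin)
  attr(out, "inside") <- array(inside, dims)
  out
}

#' Generate synthetic chessboard calibration views
#'
#' Places a planar chessboard at random valid poses in front of the camera
#' (full board inside the image, centre 350-900 mm deep, tilt up to about
#' 40 degrees), projects the inner corners through the full distortion
#' model and adds Gaussian detection noise.
#'
#' @param board_shape inner corners (cols, rows); default `c(7, 6)`.
#' @param square_size square edge, mm (default 30).
#' @param intr `camera_intrinsics` (default ToF-like).
#' @param n_views number of views (default 8).
#' @param noise_px corner detection noise SD in px (default 0).
#' @param seed integer seed.
#' @return List: `observations` (board-frame [chessboard_observation()]s),
#'   `poses` (true board->camera `rigid_transform`s), `intr`.
#' @export
make_chessboard_views <- function(board_shape = c(7, 6), square_size = 30,
                                  intr = NULL, n_views = 8, noise_px = 0,
                                  seed = 1) {
  if (is.null(intr)) intr <- camera_intrinsics(250, 250, 88, 72)
  stopifnot(n_views >= 1)
  nx <- board_shape[1]; ny <- board_shape[2]
  bx <- (seq_len(nx) - (nx + 1) / 2) * square_size
  by <- (seq_len(ny) - (ny + 1) / 2) * square_size
  corners <- as.matrix(expand.grid(X = bx, Y = by))
  corners3 <- cbind(corners, 0)
  with_seed(seed, {
    observations <- list()
    poses <- list()
    for (v in seq_len(n_views)) {
      ok <- FALSE
      for (att in 1:500) {
        ang <- runif(3, -0.7, 0.7) * c(1, 1, 2)
        R <- rotation_about(c(1, 0, 0), ang[1]) %*%
          rotation_about(c(0, 1, 0), ang[2]) %*%
          rotation_about(c(0, 0, 1), ang[3])
        z0 <- runif(1, 350, 900)
        t <- c(runif(1, -0.25, 0.25) * z0 / intr$fx * intr$width,
               runif(1, -0.25, 0.25) * z0 / intr$fy * intr$height, z0)
        pc <- corners3 %*% t(R) + rep(1, nrow(corners3)) %o% t
        if (any(pc[, 3] <= 100)) next
        Tr <- rigid_transform(orthonormalize(R), t, "board", "C")
        uv <- project_points(intr, Tr, corners3)
        if (any(uv[, 1] < 2 | uv[, 1] > intr$width - 3 |
                  uv[, 2] < 2 | uv[, 2] > intr$height - 3)) next
        uv <- uv + matrix(rnorm(length(uv), 0, noise_px), nrow(uv), 2)
        observations[[v]] <- chessboard_observation(
          point_cloud(corners3, frame = "board"), uv,
          board_shape = board_shape, square_size = square_size)
        poses[[v]] <- Tr
        ok <- TRUE
        break
      }
      if (!ok) stop("make_chessboard_views: could not frame the board")
    }
    list(observations = observations, poses = poses, intr = intr)
  })
}

#' Assemble a full synthetic three-sensor scene
#'
#' Builds a phantom and everything the registration pipeline consumes: a
#' CT-like volume of it, a ToF depth frame seen from an oblique viewpoint,
#' a stylus point cloud in the tracker's global frame, chessboard
#' calibration views, and the complete ground-truth pose chain (camera to
#' camera-marker `C -> Z`, time-indexed marker pose `Z -> G`, phantom to
#' global).  The exported chain satisfies: composing `Z -> G` after
#' `C -> Z` maps simulated camera-frame points onto their global positions.
#'
#' @param kind phantom kind (see [make_phantom()]).
#' @param seed master seed; every sub-generator derives from it.
#' @param sigma_z ToF depth noise SD, mm (default 5).
#' @param stylus_sigma stylus noise SD, mm (default 0.25).
#' @param n_stylus stylus sample count (default 2000).
#' @param spacing CT voxel spacing, mm (default 1).
#' @param view_elevation_deg camera elevation above the horizontal plane of
#'   the phantom, degrees (default 55; oblique views keep most of the
#'   surface visible).
#' @return A `synthetic_scene` list: `mesh`, `volume`, `tof` (frame +
#'   truth), `stylus`, `calib` (chessboard views), `intr`, and `truth`
#'   (poses `T_phantom_G`, `T_G_C`, `T_C_Z`, `T_Z_G`, marker pose
#'   timestamp).
#' @export
make_scene <- function(kind = "femur_like", seed = 1, sigma_z = 5,
                       stylus_sigma = 0.25, n_stylus = 2000, spacing = 1,
                       view_elevation_deg = 55) {
  mesh <- make_phantom(kind, seed = seed)
  intr <- camera_intrinsics(250, 250, 88, 72)
  truth <- with_seed(seed + 1000L, {
    # phantom placed near the tracker origin with a modest random attitude
    Rp <- rotation_about(c(0, 0, 1), runif(1, -pi, pi)) %*%
      rotation_about(c(1, 0, 0), runif(1, -0.15, 0.15))
    tp <- c(runif(2, -50, 50), runif(1, 0, 30))
    T_phantom_G <- rigid_transform(orthonormalize(Rp), tp, "phantom", "G")
    # camera looks at the phantom centre from an oblique elevation
    el <- view_elevation_deg * pi / 180
    az <- runif(1, -pi, pi)
    cam_pos <- tp + 800 * c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
    zc <- (tp - cam_pos); zc <- zc / sqrt(sum(zc^2))   # optical axis
    up <- c(0, 0, 1)
    xc <- c(zc[2] * up[3] - zc[3] * up[2],
            zc[3] * up[1] - zc[1] * up[3],
            zc[1] * up[2] - zc[2] * up[1])
    xc <- xc / sqrt(sum(xc^2))
    yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
            zc[3] * xc[1] - zc[1] * xc[3],
            zc[1] * xc[2] - zc[2] * xc[1])
    Rgc <- rbind(xc, yc, zc)       # G -> C rotation (rows = camera axes)
    T_G_C <- rigid_transform(orthonormalize(Rgc),
                             -as.numeric(Rgc %*% cam_pos), "G", "C")
    # camera marker: a fixed random transform between camera and marker
    T_C_Z <- rigid_transform(random_rotation(), runif(3, -60, 60), "C", "Z")
    # marker pose observed by the tracker: consistent closure of the chain
    T_Z_G <- compose_transforms(invert_transform(T_G_C),
                                invert_transform(T_C_Z))
    list(T_phantom_G = T_phantom_G, T_G_C = T_G_C, T_C_Z = T_C_Z,
         T_Z_G = tracked_pose(T_Z_G, timestamp = 0))
  })
  T_phantom_C <- compose_transforms(truth$T_G_C, truth$T_phantom_G)
  tof <- simulate_tof(mesh, intr, pose = T_phantom_C,
                      noise = list(sigma_z = sigma_z), seed = seed + 1L)
  stylus <- simulate_stylus(mesh, n_points = n_stylus,
                            noise_sigma = stylus_sigma,
                            pose = truth$T_phantom_G, seed = seed + 2L)
  volume <- voxelize_ct(mesh, spacing = spacing, seed = seed + 3L)
  calib <- make_chessboard_views(intr = intr, seed = seed + 4L)
  structure(list(mesh = mesh, volume = volume, tof = tof, stylus = stylus,
                 calib = calib, intr = intr, truth = truth,
                 kind = kind, seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene '%s', seed %d>\n", x$kind, x$seed))
  invisible(x)
}
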