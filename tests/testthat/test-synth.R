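# Synthetic-scene generator: phantoms, depth frames, stylus sweeps, CT
# voxelization, chessboard views, and the exported ground-truth pose chain.

test_that("sphere phantoms are exact and all kinds are watertight", {
  sph <- make_phantom("sphere", radius = 40)
  expect_lt(max(abs(sqrt(rowSums(sph$vertices^2)) - 40)), 1e-9)
  for (kind in c("femur_like", "limb_like", "head_like", "breast_like",
                 "sphere")) {
    mesh <- make_phantom(kind, seed = 2, subdiv = 2)
    F <- mesh$faces
    edges <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    expect_true(all(table(key) == 2))  # every edge shared by exactly 2 faces
    expect_identical(nrow(F), 2L * nrow(mesh$vertices) - 4L)  # closed genus 0
  }
  expect_error(make_phantom("banana"), "arg")
})

test_that("phantom generation is deterministic in the seed", {
  a <- make_phantom("femur_like", seed = 5, subdiv = 2)
  b <- make_phantom("femur_like", seed = 5, subdiv = 2)
  c <- make_phantom("femur_like", seed = 6, subdiv = 2)
  expect_identical(a$vertices, b$vertices)
  expect_gt(max(abs(a$vertices - c$vertices)), 0.1)
})

test_that("noise-free depth of an on-axis sphere matches ray geometry", {
  mesh <- make_phantom("sphere", radius = 40)
  sim <- simulate_tof(mesh, noise = list(sigma_z = 0, flying = FALSE),
                      seed = 1)
  # principal-point pixel: u = cx = 88, v = cy = 72 (0-based), so
  # [row 73, col 89]; the ray hits the sphere at 800 - 40 mm
  expect_equal(sim$frame$xyz[73, 89, 3], 760, tolerance = 1e-6)
  expect_equal(sim$frame$xyz[73, 89, 1], 0, tolerance = 1e-6)
})

test_that("flying pixels stay inside the silhouette band and determinism holds", {
  mesh <- make_phantom("femur_like", seed = 3, subdiv = 3)
  sim1 <- simulate_tof(mesh, seed = 9)
  sim2 <- simulate_tof(mesh, seed = 9)
  expect_identical(sim1$frame$xyz, sim2$frame$xyz)
  expect_identical(sim1$frame$confidence, sim2$frame$confidence)
  sim3 <- simulate_tof(mesh, seed = 10)
  expect_gt(max(abs(sim1$frame$xyz - sim3$frame$xyz)), 0)

  M <- sim1$truth$mask
  H <- nrow(M); W <- ncol(M)
  grow <- function(A) {
    B <- A
    B[-1, ] <- B[-1, ] | A[-H, ]; B[-H, ] <- B[-H, ] | A[-1, ]
    B[, -1] <- B[, -1] | A[, -W]; B[, -W] <- B[, -W] | A[, 1:(W - 1)]
    B
  }
  band <- grow(grow(M)) & grow(grow(!M))
  expect_true(all(band[sim1$truth$flying]))
  expect_true(all(sim1$frame$confidence[sim1$truth$flying] < 0.2))
})

test_that("stylus sweeps lie on the surface and honour their arguments", {
  mesh <- make_phantom("sphere", radius = 40)
  st <- simulate_stylus(mesh, n_points = 500, noise_sigma = 0, seed = 2)
  expect_identical(n_points(st), 500L)
  expect_identical(st$frame, "G")
  expect_lt(max(abs(sqrt(rowSums(st$points^2)) - 40)), 1e-6)
  a <- simulate_stylus(mesh, n_points = 200, seed = 3)
  b <- simulate_stylus(mesh, n_points = 200, seed = 3)
  c <- simulate_stylus(mesh, n_points = 200, seed = 4)
  expect_identical(a$points, b$points)
  expect_gt(max(abs(a$points - c$points)), 0)
})

test_that("voxelized volumes reproduce the mesh volume fraction", {
  mesh <- make_phantom("head_like", seed = 7, subdiv = 3)
  vol <- voxelize_ct(mesh, spacing = 2, seed = 8)
  inside <- attr(vol, "inside")
  # Monte-Carlo volume oracle over the voxel-covered box (each voxel centre
  # represents a cell extending half a spacing beyond the centre range)
  set.seed(99)
  n <- 200000
  lo <- vol$origin - vol$spacing / 2
  hi <- vol$origin + (dim(vol$data) - 0.5) * vol$spacing
  P <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
             runif(n, lo[3], hi[3]))
  radial <- attr(mesh, "radial")
  nrm <- sqrt(rowSums(P^2))
  mc <- mean(nrm <= radial(P / nrm))
  expect_lt(abs(mean(inside) - mc) / mc, 0.02)
})

test_that("air regions of synthetic CT stay below -800 HU on average", {
  mesh <- make_phantom("sphere", radius = 25)
  vol <- voxelize_ct(mesh, spacing = 1.5, seed = 9)
  inside <- attr(vol, "inside")
  expect_lt(mean(vol$data[!inside]), -800)
  # deep interior (partial-volume blur only affects a boundary shell)
  dims <- dim(vol$data)
  ax <- lapply(1:3, function(i) vol$origin[i] + (seq_len(dims[i]) - 1) *
                 vol$spacing[i])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  expect_gt(mean(vol$data[r2 <= 18^2]), 0)
  # air far from the object keeps its class mean
  expect_lt(mean(vol$data[r2 >= 32^2]), -950)
})

test_that("chessboard corners stay in frame and noiseless views validate to zero", {
  views <- make_chessboard_views(n_views = 5, noise_px = 0, seed = 11)
  for (i in seq_along(views$observations)) {
    ob <- views$observations[[i]]
    expect_true(all(ob$corners_2d[, 1] >= 0 &
                      ob$corners_2d[, 1] <= views$intr$width - 1))
    expect_true(all(ob$corners_2d[, 2] >= 0 &
                      ob$corners_2d[, 2] <= views$intr$height - 1))
    rep <- validate_projection(views$intr, views$poses[[i]], ob$corners_3d,
                               ob$corners_2d)
    expect_lt(rep$mean_error, 1e-9)
  }
})

test_that("the exported pose chain closes: C -> Z -> G equals direct C -> G", {
  sc <- make_scene("sphere", seed = 21, sigma_z = 0)
  chain <- compose_transforms(sc$truth$T_Z_G$transform, sc$truth$T_C_Z)
  direct <- invert_transform(sc$truth$T_G_C)
  pts <- point_cloud(matrix(rnorm(300, sd = 200), 100, 3), "C")
  p1 <- apply_transform(chain, pts)
  p2 <- apply_transform(direct, pts)
  expect_lt(max(abs(p1$points - p2$points)), 1e-9)
})

test_that("scenes are reproducible from their seed", {
  s1 <- make_scene("sphere", seed = 31)
  s2 <- make_scene("sphere", seed = 31)
  expect_identical(s1$stylus$points, s2$stylus$points)
  expect_identical(s1$tof$frame$xyz, s2$tof$frame$xyz)
  expect_identical(s1$volume$data, s2$volume$data)
  expect_identical(as_matrix(s1$truth$T_C_Z), as_matrix(s2$truth$T_C_Z))
})
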