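---
title: "Multi-sensor surface registration: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-sensor surface registration: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfreg)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, and
the design choices made where the design was genuinely open.

## The problem

Image-guided interventions need every data source displayed in one
coordinate system.  Here three sources observe the same rigid object: a
pre-operative CT-like volume, a time-of-flight (ToF) depth camera
delivering per-pixel 3-D coordinates plus amplitude and confidence at low
resolution (176×144 by default), and a stylus tracked by an optical
navigation system, slid over the surface to sample points directly in the
tracker's global frame.  The package turns each source into a point cloud
of the object surface, registers every pair rigidly, and quantifies the
residual misalignment.

The central modelling assumption is **rigidity**: the object does not
deform between acquisitions, so all inter-sensor maps are rotations plus
translations (millimetres throughout, the tracker-native unit).
Non-rigid anatomy, motion and time synchronisation are out of scope.

## Frame algebra

Transforms are first-class objects with frame labels, and every operation
checks them.  This is deliberate friction: with three sensors and four
frames (`CT`, `C` camera, `Z` camera-marker, `G` global) the cheapest way
to produce a silently wrong registration is to apply a valid matrix to a
cloud in the wrong frame.  Rotations are validated to 1e-9 on
orthonormality at construction; `orthonormalize()` (SVD polar projection)
is the explicit repair path for drifted matrices, and it refuses
reflections and matrices further than 1e-3 from a rotation, which indicate
corrupt calibration rather than round-off.

The camera-to-marker calibration `T_C^Z` is the persistent product of the
calibration stage: it survives camera and tracker motion, whereas plain
extrinsics `T_G^C` are valid only for one rig arrangement.  A camera point
reaches the global frame through the chain `(T_Z^G)_τ ∘ T_C^Z`, with the
marker pose re-read from the tracker at each acquisition time τ.

## Camera model and calibration

The pinhole model with an OpenCV-style 5-coefficient radial–tangential
distortion vector `(k1, k2, p1, p2, k3)` is used for projection and its
inverse.  Pixel convention: `u` rightward, `v` downward, origin at the
centre of the top-left pixel; the synthetic sensor is 176×144 px with
`fx = fy = 250` px (≈ 39°×32° field of view, the class of compact ToF
devices).  `k3` defaults to zero and is excluded from refinement — with a
narrow field of view and a 7×6 corner grid the sixth-order term is not
identifiable and only destabilises the fit.

Intrinsic calibration is Zhang's method: a DLT homography per chessboard
view (with Hartley normalisation), closed-form intrinsics from the
absolute-conic constraints, then joint Levenberg–Marquardt refinement
(`minpack.lm`) of intrinsics, distortion and per-view poses on the total
reprojection error.  At least three views at distinct orientations are
required; the synthetic default is eight views of a 7×6-corner, 30 mm
board — a stated choice, since typical rigs are calibrated from a handful
of hand-held views.

Pose from known 3-D/2-D correspondences (PnP) initialises by DLT on the
3×4 projection matrix for general configurations.  For **coplanar** point
sets — the chessboard, i.e. the only configuration the calibration
workflow actually produces — the DLT is degenerate, so the pose is instead
initialised from the board-plane homography; only collinear configurations
are rejected as errors.  Refinement is Levenberg–Marquardt on reprojection
error with the distortion model included, iterated to a relative RMSE
change below 1e-10 or 100 iterations.

Calibration quality is validated by projecting tracker-measured test
points through the solved model and comparing with their image detections
(mean ± SD pixel distance).  Points that fall behind the camera are
excluded *and reported*, never silently dropped.  Validation through a
composed pose (global points carried into the marker frame first) is
algebraically identical to validating in the marker frame directly; a test
asserts that equivalence to 1e-9 px.

## CT segmentation

Phantom-style objects (mean density above 0 HU) against air (≈ −1000 HU)
are separated by Otsu's threshold on a 256-bin histogram over the data
range.  For well-separated classes the between-class variance is flat
across the empty gap between the modes; the canonical handling — returning
the midpoint of the tying plateau, as classic implementations do — is
used, and an exhaustive-search oracle with the same tie rule verifies the
maximisation.  On this package's synthetic two-Gaussian mixture
(object 50 ± 50 HU, air −1000 ± 30 HU, ~10 % object voxels, 1-voxel
partial-volume blur) the threshold lands near −490 HU, i.e. roughly midway
between the class tails.  Real phantom CTs can yield thresholds 50–100 HU
lower, because low-density materials and partial-volume voxels pull the
upper class's mean far below its nominal density — a feature of real
attenuation distributions that a two-Gaussian mixture deliberately does
not model.

The binary pipeline after thresholding: closing with a ball of radius 2
voxels (bridges surface pitting without merging nearby structures),
largest 26-connected component (removes specks and the scanner table),
per-slice hole filling (phantoms are hollow; only the outer surface is
wanted), then surface extraction.  The registration pipeline consumes
points, not meshes, so the extraction returns the **vertex set of the
0.5-level isosurface** of the mask: the midpoint of every grid edge
joining a foreground and a background voxel.  These are exactly the
marching-cubes vertex positions at iso 0.5; the triangle topology is
simply never built.  Vertices are scaled by the voxel spacing and offset
by the volume origin, so the surface lives in scanner millimetres.

## ToF segmentation

Depth inhomogeneity at object silhouettes produces "flying pixels" whose
range mixes foreground and background.  The sensor's confidence map is the
tool against them: pixels below `confidence_min = 0.3` are discarded
before clustering (the simulator assigns flying pixels confidence below
0.2, so the gate removes them by construction; on real devices the gate
level is a tunable).

Remaining pixels are clustered by **weighted fuzzy c-means**: features are
the per-pixel camera-frame coordinates and amplitude, each standardized,
giving a 4-vector `(x, y, z, a)`; weights are the per-pixel confidences.
The member-ship update is `u_ij ∝ d_ij^(−2/(m−1))` normalised over
clusters and the centre update is the weight-and-membership weighted mean,
which makes the objective `Σ_i Σ_j w_i u_ij^m ‖x_i − c_j‖²` non-increasing
— asserted at every iteration.  Defaults `m = 2`, `tol = 1e-6`,
`max_iter = 300` are the standard fuzzy-c-means settings.  Initialisation
is a weighted k-means++ scheme, fully determined by the seed.  The object
cluster is chosen as the one with the highest mean amplitude, with nearest
mean depth as a tie-break within 5 % — on an operating-table scene the
object of interest is the bright, near surface.

Two open readings were fixed as follows: clustering happens in 3-D camera
space (not 2-D image space), because the point coordinates are what
registration consumes; and the confidence map enters as the WFCM weight
(not as a feature), because reliability should modulate a pixel's
influence, not its position in feature space.  Both choices sit behind
arguments (`amplitude_scale`, `weights`) so they can be revisited.

## Trimmed ICP

The six classic steps, with these instantiations: all segmented points are
used (no subsampling); matching is exact nearest neighbour through a
package-owned k-d tree (exact ties resolve to the lowest target index, so
results match a first-wins linear scan bit for bit); pair weights are
constant; the worst 5 % of pairs by distance are rejected *each iteration*
from fresh correspondences; the error metric is RMSE over kept pairs; and
the update is the closed-form Kabsch solution with determinant correction
(a reflected optimum is never returned, even for planar degenerate-ish
clouds).  Convergence: relative RMSE change below 1e-8 or 200 iterations;
the post-update RMSE sequence is non-increasing up to 1e-9 slack and is
returned in full for diagnostics.

Trimming is for outliers, not a free lunch: on noiseless, fully
overlapping clouds the 5 % rejection discards exactly the extremal points
that carry the orientation signal, and the greedy iteration can stall a
few hundredths of a radian from the truth.  The package therefore leaves
`trim` a per-call parameter: ground-truth recovery experiments run with
`trim = 0` (there is nothing to reject), while any acquisition containing
gross outliers or partial overlap keeps the default 0.05.  This behaviour
is measured, not hypothesised — see the registration tests.

ICP needs a pre-alignment to avoid gross local minima, particularly
symmetry flips on near-symmetric objects.  Three initialisations are
offered: identity; centroid + principal axes (all four proper sign
assignments scored by trimmed nearest-distance, best kept); and the
calibration chain, which carries the ToF cloud into the global frame with
no data-driven step at all.  The exact pre-alignment procedure of a
physical rig is hardware-specific; these three are offered without
claiming fidelity to any particular one.

Registration is **not symmetric**: `icp(A, B)` need not invert `icp(B, A)`
on partial-overlap data, which is precisely why evaluation reports both
directions of every pair.

## Distance metrics

Directed Hausdorff and MAD are computed from one nearest-distance pass
(k-d tree, exact).  Percentile trimming drops the `⌈p_m · n⌉` largest
per-point distances before taking max/mean; `p_m = 0` reproduces the plain
definitions bit for bit.  Rounding up is a stated choice — the field's
tables never define the rounding — as is trimming by point count rather
than distance mass.  Ties at the cut keep the lower point index, making
reports deterministic.  Invariants asserted in tests: HD ≥ MAD always;
both non-increasing in `p_m`; rigid invariance to a common transform
within 1e-9.

## The synthetic scene generator

The generator stands in for the physical rig and defines the package's
study conditions:

* **Phantoms** — superellipsoids radially modulated by a seeded smooth bump
  field, built on a subdivided icosahedron (watertight by construction;
  a test audits that every edge is shared by exactly two triangles).  The
  shapes are deliberately non-symmetric, because near-symmetric objects
  make ICP flip; an exact sphere is kept for analytic checks.  All
  phantoms are star-shaped and carry their radial function, used for exact
  surface sampling and inside tests.
* **ToF frames** — one ray per pixel through the pinhole model,
  triangle-exact intersection (analytic for the sphere), a background
  plane 300 mm behind the phantom, amplitude falling with squared range
  and incidence angle, confidence high on the object interior and low at
  edges.  Depth noise is Gaussian **along the ray** with σ_z = 5 mm by
  default — ToF range error dominates lateral error, and 5 mm represents
  the sub-centimetre class of such sensors; lateral noise defaults to 0.
  Pixels adjacent to the silhouette become flying pixels: mixed
  foreground/background range and confidence drawn below 0.2.
* **Stylus clouds** — meridian-style sweep strokes with seeded wobble,
  sampled exactly on the radial surface, plus isotropic Gaussian noise of
  0.25 mm (tracked-tool class accuracy; a chosen figure).  Strokes stop at
  polar angle 135°, leaving the resting base unsampled, which produces the
  partial-coverage asymmetry visible in the evaluation tables.
* **CT volumes** — per-voxel-centre inside test, HU drawn from
  object 50 ± 50 HU and air −1000 ± 30 HU, then a 1-voxel Gaussian blur as
  partial-volume surrogate.  1 mm isotropic spacing by default.
* **Chessboard views** — random valid poses keeping the whole board in
  frame, full-distortion projection, optional Gaussian corner noise.

Everything is deterministic in the seed, and every pose of the chain
(`phantom→G`, `G→C`, `C→Z`, `Z→G`) is exported, so tests can compare
results against truth rather than against other outputs.  What the
generator does **not** emulate: multipath and wiggling error of real ToF
sensors, amplitude-dependent range bias, tracker line-of-sight dropouts,
CT beam hardening, and anatomical (non-phantom) attenuation
distributions.  Passing tests therefore demonstrate algorithmic
correctness under controlled conditions, not device-level performance.

## Problem sizes and numerical choices

The shipped experiments use phantoms of ~10–20 cm extent voxelized at
1 mm (≈ 2–3 M voxels), depth frames at 176×144, stylus clouds of 2000
points, and CT surface clouds of ~30–50 k vertices; the full six-direction
pipeline completes in well under a minute on one core.  Degenerate inputs
fail loudly: constant volumes (no Otsu threshold), empty foreground,
all-gated depth frames, fewer than 3 point pairs in the rigid solve,
collinear PnP configurations, clouds in mismatched frames.  Distance ties
everywhere resolve by lowest index.  The fuzzy-c-means reseeds a collapsed
cluster from the highest-weight farthest point and errors on repeated
collapse rather than looping forever.

## Known limitations

Rigid-only; no time interpolation of marker poses; no mesh-interpolated
(point-to-plane) distances — metrics are cloud-to-cloud, so they carry the
surface sampling density as a noise floor (≈ 0.25 mm MAD at 1 mm voxels);
the manual outlier-removal workflow is exposed only as a generic
`remove_points()` utility; and the evaluation deliberately reports
directed metrics rather than symmetric Hausdorff, matching how such
systems are audited in practice.
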