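# Thin wrappers over the compiled k-d tree.

#' Build a k-d tree over a set of 3-D points
#'
#' The tree is a static, balanced k-d tree used to accelerate all
#' nearest-neighbour queries in the package (ICP correspondence search and
#' surface-distance metrics).  Exact distance ties resolve to the lowest
#' point index, matching a first-wins linear scan.
#'
#' @param points N x 3 matrix or `point_cloud`.
#' @return An opaque handle usable with [nn_query()].
#' @export
nn_build <- function(points) {
  if (inherits(points, "point_cloud")) points <- points$points
  stopifnot(is.matrix(points), ncol(points) == 3, nrow(points) >= 1)
  storage.mode(points) <- "double"
  structure(list(tree = .kdtree_build(points), n = nrow(points)),
            class = "nn_index")
}

#' Query nearest neighbours from a prebuilt tree
#'
#' @param index handle from [nn_build()].
#' @param probes M x 3 matrix or `point_cloud` of query points.
#' @return List with `index` (1-based nearest-point indices, length M) and
#'   `distance` (Euclidean distances, mm).
#' @export
nn_query <- function(index, probes) {
  stopifnot(inherits(index, "nn_index"))
  if (inherits(probes, "point_cloud")) probes <- probes$points
  stopifnot(is.matrix(probes), ncol(probes) == 3)
  storage.mode(probes) <- "double"
  .kdtree_query(index$tree, probes)
}
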