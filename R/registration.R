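# Trimmed point-to-point ICP.
#
# The registration loop follows the classic six-step decomposition:
# (1) point selection -- all points delivered by the segmentation stage are
# used, no subsampling by default; (2) matching by nearest neighbour through
# a k-d tree; (3) constant (unit) pair weights; (4) rejection of the worst
# 5 % of pairs by Euclidean distance; (5) RMSE as the error metric; (6)
# closed-form minimisation of the RMSE over rigid motions by SVD (Kabsch).

#' Nearest-neighbour correspondences between two clouds
#'
#' For every source point, the index of its nearest target point.  The caller
#' is expected to have applied the current transform estimate so both clouds
#' are numerically in the same frame.  Exact distance ties resolve to the
#' lowest target index.
#'
#' @param source,target `point_cloud`s (or N x 3 matrices).
#' @return A `correspondences` object: `source_idx`, `target_idx`,
#'   `distances` (mm) and logical `kept` (all `TRUE` until
#'   [reject_worst()]).
#' @export
match_nearest <- function(source, target) {
  sp <- if (inherits(source, "point_cloud")) source$points else source
  tree <- nn_build(target)
  q <- nn_query(tree, sp)
  structure(list(source_idx = seq_len(nrow(sp)), target_idx = q$index,
                 distances = q$distance, kept = rep(TRUE, nrow(sp))),
            class = "correspondences")
}

#' Reject the worst fraction of correspondences
#'
#' Clears the `floor(fraction * N)` largest-distance pairs from the `kept`
#' mask, so `sum(kept) == ceiling((1 - fraction) * N)`.  Ties at the cut
#' keep the lower pair index.
#'
#' @param corr a `correspondences` object.
#' @param fraction rejection fraction in \[0, 1); default 0.05, the
#'   conventional 5 % worst-pair rejection.
#' @return The updated `correspondences`.
#' @export
reject_worst <- function(corr, fraction = 0.05) {
  stopifnot(inherits(corr, "correspondences"),
            fraction >= 0, fraction < 1)
  n <- length(corr$distances)
  drop <- floor(fraction * n)
  kept <- rep(TRUE, n)
  if (drop > 0) {
    ord <- order(corr$distances, seq_len(n))  # ties: lower index first (kept)
    kept[ord[(n - drop + 1):n]] <- FALSE
  }
  corr$kept <- kept
  corr
}

#' Least-squares rigid transform between paired point sets (Kabsch)
#'
#' Closed-form minimiser of `sum ||R s_i + t - t_i||^2`: centroid
#' subtraction, SVD of the cross-covariance, and the determinant sign
#' correction that excludes reflections, so `det(R) = +1` always.
#'
#' @param source_pts,target_pts paired N x 3 matrices (N >= 3,
#'   non-collinear).
#' @param frame_from,frame_to frame labels for the returned transform.
#' @return A `rigid_transform`.
#' @export
estimate_rigid_svd <- function(source_pts, target_pts,
                               frame_from = "A", frame_to = "B") {
  source_pts <- as.matrix(source_pts); target_pts <- as.matrix(target_pts)
  stopifnot(nrow(source_pts) == nrow(target_pts), ncol(source_pts) == 3)
  n <- nrow(source_pts)
  if (n < 3) stop("estimate_rigid_svd: need at least 3 point pairs")
  cs <- colMeans(source_pts); ct <- colMeans(target_pts)
  S <- sweep(source_pts, 2, cs); Tm <- sweep(target_pts, 2, ct)
  H <- crossprod(S, Tm)  # 3x3 cross-covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("estimate_rigid_svd: degenerate (collinear) configuration")
  d <- det(sv$v %*% t(sv$u))
  R <- sv$v %*% diag(c(1, 1, sign(d))) %*% t(sv$u)
  t <- ct - as.numeric(R %*% cs)
  rigid_transform(orthonormalize(R), t, frame_from, frame_to)
}

#' Iterative closest point registration with worst-pair trimming
#'
#' Repeats: apply the current transform to the source, match each source
#' point to its nearest target point (k-d tree), weight pairs uniformly,
#' reject the worst `trim` fraction by distance, re-estimate the rigid
#' motion on the kept pairs by SVD, and fold the update into the running
#' transform.  Iteration stops when the relative RMSE change over kept
#' pairs drops below `tol`, or after `max_iter` sweeps.  The RMSE recorded
#' each iteration is evaluated after the update, and is non-increasing up
#' to numerical slack.
#'
#' @param source,target `point_cloud`s with at least 3 points each.
#' @param init `rigid_transform` mapping the source frame into the target
#'   frame (pre-alignment); defaults to identity over the source/target
#'   frame pair.  See [prealign_axes()] for a data-driven initial guess.
#' @param trim worst-pair rejection fraction per iteration (default 0.05).
#' @param tol relative RMSE-change convergence threshold (default 1e-8).
#' @param max_iter iteration cap (default 200).
#' @return An `icp_result`: `transform` (full source -> target map including
#'   `init`), `rmse_history` (mm, one entry per iteration), `iterations`,
#'   `converged`, and the final `correspondences`.
#' @export
icp <- function(source, target, init = NULL, trim = 0.05, tol = 1e-8,
                max_iter = 200) {
  stopifnot(inherits(source, "point_cloud"), inherits(target, "point_cloud"))
  if (n_points(source) < 3 || n_points(target) < 3)
    stop("icp: both clouds need at least 3 points")
  if (is.null(init)) init <- rigid_transform(diag(3), c(0, 0, 0),
                                             source$frame, target$frame)
  stopifnot(inherits(init, "rigid_transform"))
  if (!identical(init$frame_from, source$frame) ||
      !identical(init$frame_to, target$frame))
    stop(sprintf("icp: init maps '%s' -> '%s' but clouds are '%s' and '%s'",
                 init$frame_from, init$frame_to, source$frame, target$frame))

  tree <- nn_build(target)
  tp <- target$points
  Tcur <- init
  rmse_history <- numeric(0)
  converged <- FALSE
  corr <- NULL
  for (it in seq_len(max_iter)) {
    sp <- apply_transform(Tcur, source$points)
    q <- nn_query(tree, sp)
    corr <- structure(list(source_idx = seq_len(nrow(sp)),
                           target_idx = q$index, distances = q$distance,
                           kept = rep(TRUE, nrow(sp))),
                      class = "correspondences")
    corr <- reject_worst(corr, trim)
    keep <- which(corr$kept)
    if (length(keep) < 3)
      stop(structure(class = c("icp_degenerate", "error", "condition"),
                     list(message = "icp: fewer than 3 kept pairs",
                          call = sys.call(-1), last_state = Tcur)))
    if (max(corr$distances[keep]) == 0) {
      # already exactly aligned: the update is the identity
      rmse_history <- c(rmse_history, 0)
      converged <- TRUE
      break
    }
    upd <- estimate_rigid_svd(sp[keep, , drop = FALSE],
                              tp[corr$target_idx[keep], , drop = FALSE],
                              target$frame, target$frame)
    Tcur <- compose_transforms(upd, Tcur)
    # post-update RMSE over this iteration's kept pairs
    spn <- apply_transform(Tcur, source$points)[keep, , drop = FALSE]
    resid <- spn - tp[corr$target_idx[keep], , drop = FALSE]
    rmse <- sqrt(mean(rowSums(resid^2)))
    rmse_history <- c(rmse_history, rmse)
    if (rmse < 1e-12) {  # exact-alignment floor: relative change is noise
      converged <- TRUE
      break
    }
    if (it > 1) {
      prev <- rmse_history[it - 1]
      if (abs(prev - rmse) / max(prev, .Machine$double.eps) < tol) {
        converged <- TRUE
        break
      }
    }
  }
  structure(list(transform = Tcur, rmse_history = rmse_history,
                 iterations = length(rmse_history), converged = converged,
                 correspondences = corr),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result: %d iterations, %s, final RMSE %.4g mm>\n",
              x$iterations, if (x$converged) "converged" else "not converged",
              x$rmse_history[x$iterations]))
  invisible(x)
}

#' Centroid and principal-axes pre-alignment
#'
#' Coarse initial transform for ICP: translates the source centroid onto the
#' target centroid and aligns the principal axes (eigenvectors of the point
#' covariance).  Principal axes carry a sign ambiguity, so all four proper
#' (det = +1) sign assignments are evaluated and the one with the smallest
#' trimmed mean nearest-distance is returned.  Intended for clouds with a
#' distinctly non-symmetric shape; near-symmetric objects can still flip.
#'
#' @param source,target `point_cloud`s.
#' @param trim fraction of worst matches ignored when scoring candidates
#'   (default 0.2, generous to tolerate partial overlap).
#' @return A `rigid_transform` mapping `source$frame -> target$frame`.
#' @export
prealign_axes <- function(source, target, trim = 0.2) {
  sp <- source$points; tp <- target$points
  cs <- colMeans(sp); ct <- colMeans(tp)
  es <- eigen(stats::cov(sp), symmetric = TRUE)$vectors
  et <- eigen(stats::cov(tp), symmetric = TRUE)$vectors
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(et) < 0) et[, 3] <- -et[, 3]
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  tree <- nn_build(tp)
  best <- NULL; best_score <- Inf
  for (f in flips) {
    R <- et %*% diag(f) %*% t(es)
    Tc <- rigid_transform(orthonormalize(R), ct - as.numeric(R %*% cs),
                          source$frame, target$frame)
    d <- nn_query(tree, apply_transform(Tc, sp))$distance
    score <- mean(sort(d)[seq_len(ceiling((1 - trim) * length(d)))])
    if (score < best_score) { best_score <- score; best <- Tc }
  }
  best
}
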