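# Surface-distance metrics between registered point clouds.
#
# Both metrics are *directed*: they scan source points A and, for each, take
# the distance to the nearest point of target B.  The Hausdorff distance is
# the maximum of these nearest-point distances, the mean absolute distance
# (MAD) their mean.  Direction matters on partial-overlap data, so reports
# always carry both directions explicitly and no symmetric variant is
# offered.

check_metric_pair <- function(A, B) {
  stopifnot(inherits(A, "point_cloud"), inherits(B, "point_cloud"))
  if (!identical(A$frame, B$frame))
    stop(sprintf("metric: clouds in different frames ('%s' vs '%s')",
                 A$frame, B$frame))
}

nearest_distances <- function(A, B) {
  check_metric_pair(A, B)
  nn_query(nn_build(B), A)$distance
}

#' Directed Hausdorff distance between point clouds
#'
#' `max_i min_j ||a_i - b_j||` in millimetres.  Exact (k-d tree accelerated,
#' no approximation).  Note `directed_hausdorff(A, B)` generally differs from
#' `directed_hausdorff(B, A)`.
#'
#' @param A,B `point_cloud`s in the same frame.
#' @return Distance in mm.
#' @export
directed_hausdorff <- function(A, B) max(nearest_distances(A, B))

#' Mean absolute surface distance between point clouds
#'
#' Mean over points of `A` of the distance to the nearest point of `B` (mm).
#'
#' @param A,B `point_cloud`s in the same frame.
#' @return Distance in mm.
#' @export
mad_distance <- function(A, B) mean(nearest_distances(A, B))

#' Percentile-trimmed Hausdorff and MAD
#'
#' Computes the per-point nearest distances from `A` to `B` once, then for
#' each rejection fraction `p_m` drops the `ceiling(p_m * n)` largest
#' distances (the worst matches) and reports the maximum (HD) and mean (MAD)
#' of the survivors.  `p_m = 0` reproduces the untrimmed definitions
#' bit-for-bit.  Ties at the cut keep the lower point index.
#'
#' @param A,B `point_cloud`s in the same frame.
#' @param pms rejection fractions in \[0, 1); default `c(0.10, 0.03, 0)`,
#'   the three levels conventionally reported.
#' @param names optional pair of cloud names for the report label.
#' @return A `distance_report`: list with `pair`, `per_pm` (named list of
#'   `list(hd, mad)` keyed by percentage), and point counts.
#' @export
trimmed_metrics <- function(A, B, pms = c(0.10, 0.03, 0),
                            names = c("A", "B")) {
  stopifnot(all(pms >= 0), all(pms < 1))
  d <- nearest_distances(A, B)
  n <- length(d)
  ord <- order(d, seq_along(d))  # ascending; ties by index (lower kept)
  per_pm <- lapply(pms, function(p) {
    drop <- ceiling(p * n)
    if (n - drop < 1)
      stop(sprintf("trimmed_metrics: p_m = %g leaves no points", p))
    keep <- ord[seq_len(n - drop)]
    if (drop == 0) list(hd = max(d), mad = mean(d))
    else list(hd = max(d[keep]), mad = mean(d[keep]))
  })
  names(per_pm) <- sprintf("%g%%", pms * 100)
  structure(list(pair = names, per_pm = per_pm,
                 n_points_A = n_points(A), n_points_B = n_points(B)),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("<distance_report: %s to %s (n=%d vs %d)>\n",
              x$pair[1], x$pair[2], x$n_points_A, x$n_points_B))
  for (p in names(x$per_pm))
    cat(sprintf("  p_m=%-5s HD = %8.3f mm   MAD = %8.3f mm\n",
                p, x$per_pm[[p]]$hd, x$per_pm[[p]]$mad))
  invisible(x)
}

#' Directed distance reports for every ordered pair of clouds
#'
#' For k named clouds produces the k*(k-1) directed reports "X to Y"
#' (meaning A = X, B = Y), mirroring the both-directions-per-pair layout
#' conventional for asymmetric surface metrics.
#'
#' @param clouds named list of at least two `point_cloud`s in a common frame.
#' @param pms rejection fractions, as in [trimmed_metrics()].
#' @return List of `distance_report`s, named `"X to Y"`.
#' @export
pairwise_report <- function(clouds, pms = c(0.10, 0.03, 0)) {
  stopifnot(is.list(clouds), length(clouds) >= 2, !is.null(names(clouds)))
  nm <- names(clouds)
  out <- list()
  for (i in seq_along(clouds)) for (j in seq_along(clouds)) {
    if (i == j) next
    lab <- sprintf("%s to %s", nm[i], nm[j])
    out[[lab]] <- trimmed_metrics(clouds[[i]], clouds[[j]], pms,
                                  names = c(nm[i], nm[j]))
  }
  out
}

#' Flatten distance reports into a data frame
#'
#' One row per directed pair, columns `hd_<pm>` / `mad_<pm>` per trim level;
#' the layout used for CSV export of evaluation tables.
#'
#' @param reports list of `distance_report`s from [pairwise_report()].
#' @return A `data.frame`.
#' @export
report_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    lv <- gsub("%", "", names(r$per_pm))
    vals <- unlist(lapply(r$per_pm, function(x) c(x$hd, x$mad)))
    names(vals) <- as.vector(rbind(paste0("hd_", lv), paste0("mad_", lv)))
    data.frame(pair = paste(r$pair, collapse = " to "), t(vals),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
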