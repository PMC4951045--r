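# End-to-end pipeline: calibrate / segment / register / evaluate, mirroring
# the experimental workflow of a three-sensor rig (CT volume, ToF camera,
# tracked stylus).

#' Pipeline configuration
#'
#' Validated container of every tunable used by [run_pipeline()].  Unknown
#' keys are rejected; every numeric parameter is range-checked here so a
#' typo fails fast rather than mid-pipeline.
#'
#' @param kind phantom kind for the synthetic scene (see [make_phantom()]).
#' @param seed master seed for the synthetic scene.
#' @param sigma_z ToF depth noise SD, mm (>= 0).
#' @param stylus_sigma stylus noise SD, mm (>= 0).
#' @param confidence_min ToF confidence gate in \[0, 1\].
#' @param wfcm_seed seed for the fuzzy clustering initialization.
#' @param trim ICP worst-pair rejection fraction in \[0, 1).
#' @param tol ICP relative-RMSE convergence tolerance (> 0).
#' @param max_iter ICP iteration cap (>= 1).
#' @param init ICP pre-alignment: `"calibration"` (use the camera/marker
#'   chain for the ToF cloud and principal axes for CT), `"axes"`, or
#'   `"identity"`.
#' @param pms metric trim fractions in \[0, 1).
#' @param spacing CT voxel spacing, mm.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(kind = "femur_like", seed = 1, sigma_z = 5,
                            stylus_sigma = 0.25, confidence_min = 0.3,
                            wfcm_seed = 1, trim = 0.05, tol = 1e-8,
                            max_iter = 200,
                            init = c("calibration", "axes", "identity"),
                            pms = c(0.10, 0.03, 0), spacing = 1) {
  init <- match.arg(init)
  stopifnot(sigma_z >= 0, stylus_sigma >= 0,
            confidence_min >= 0, confidence_min <= 1,
            trim >= 0, trim < 1, tol > 0, max_iter >= 1,
            all(pms >= 0), all(pms < 1), spacing > 0)
  structure(list(kind = kind, seed = as.integer(seed), sigma_z = sigma_z,
                 stylus_sigma = stylus_sigma,
                 confidence_min = confidence_min,
                 wfcm_seed = as.integer(wfcm_seed), trim = trim, tol = tol,
                 max_iter = as.integer(max_iter), init = init,
                 pms = pms, spacing = spacing),
            class = "pipeline_config")
}

#' Serialize / parse a pipeline configuration
#'
#' JSON round-trip: `parse_config(serialize_config(cfg))` reproduces `cfg`.
#'
#' @param config a `pipeline_config`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (or `path` invisibly).
#' @export
serialize_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname serialize_config
#' @param json JSON string or file path to parse.
#' @export
parse_config <- function(json) {
  x <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
       else jsonlite::fromJSON(json)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("parse_config: unknown keys: ", paste(extra, collapse = ", "))
  do.call(pipeline_config, x)
}

#' Remove points from a cloud by index
#'
#' Generic point-removal utility (e.g. manual outlier cleanup).  The
#' removed count is recorded in the `provenance` attribute.
#'
#' @param cloud a `point_cloud`.
#' @param indices integer indices to drop (empty is a no-op).
#' @return The reduced `point_cloud`.
#' @export
remove_points <- function(cloud, indices) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!length(indices)) return(cloud)
  indices <- as.integer(indices)
  if (any(indices < 1 | indices > n_points(cloud)))
    stop("remove_points: index out of range")
  keep <- setdiff(seq_len(n_points(cloud)), indices)
  if (!length(keep)) stop("remove_points: no points left")
  out <- point_cloud(cloud$points[keep, , drop = FALSE], cloud$frame,
                     cloud$amplitude[keep], cloud$confidence[keep])
  attr(out, "provenance") <-
    sprintf("removed %d of %d points", length(indices), n_points(cloud))
  out
}

#' Run the full synthetic three-sensor registration pipeline
#'
#' Generates (or accepts) a synthetic scene, then: extracts the CT surface,
#' segments the ToF frame, carries the ToF cloud into the tracker global
#' frame through the calibration chain (marker pose composed with the
#' camera-to-marker calibration), pre-aligns the CT surface, runs one
#' trimmed ICP per ordered pair of sensors (six runs: each direction of
#' CT/Opt, Opt/ToF, CT/ToF), and evaluates each registered pair with
#' percentile-trimmed Hausdorff/MAD metrics.
#'
#' @param config a [pipeline_config()].
#' @param scene optional pre-built [make_scene()] output (otherwise built
#'   from `config`).
#' @param verbose print per-stage progress (default FALSE).
#' @return A `pipeline_result`: `clouds` (CT/Opt/ToF in the global frame,
#'   post-registration per direction), `reports` (six directed
#'   `distance_report`s), `icp` (six `icp_result`s), `scene`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), scene = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.null(scene)) {
    say("stage synth: scene kind=%s seed=%d", config$kind, config$seed)
    scene <- stage("synth",
                   make_scene(config$kind, seed = config$seed,
                              sigma_z = config$sigma_z,
                              stylus_sigma = config$stylus_sigma,
                              spacing = config$spacing))
  }
  say("stage segment-ct")
  ct <- stage("segment-ct", segment_ct(scene$volume, frame = "CT"))
  say("stage segment-tof")
  tof_c <- stage("segment-tof",
                 segment_tof(scene$tof$frame,
                             confidence_min = config$confidence_min,
                             seed = config$wfcm_seed))
  # ToF cloud into the global frame through the calibration chain
  T_C_G <- compose_transforms(scene$truth$T_Z_G$transform, scene$truth$T_C_Z)
  tof_g <- apply_transform(T_C_G, tof_c)
  opt <- scene$stylus
  say("stage prealign")
  ct_init <- stage("prealign", switch(config$init,
    calibration = prealign_axes(ct, opt),  # CT has no calibration link
    axes = prealign_axes(ct, opt),
    identity = rigid_transform(diag(3), c(0, 0, 0), ct$frame, opt$frame)))
  ct_g <- apply_transform(ct_init, ct)

  clouds <- list(CT = ct_g, Opt = opt, ToF = tof_g)
  pairs <- list(c("CT", "Opt"), c("Opt", "CT"), c("Opt", "ToF"),
                c("ToF", "Opt"), c("CT", "ToF"), c("ToF", "CT"))
  icps <- list()
  reports <- list()
  for (pr in pairs) {
    lab <- sprintf("%s to %s", pr[1], pr[2])
    say("stage register: %s", lab)
    res <- stage(paste0("register ", lab),
                 icp(clouds[[pr[1]]], clouds[[pr[2]]],
                     trim = config$trim, tol = config$tol,
                     max_iter = config$max_iter))
    icps[[lab]] <- res
    moved <- apply_transform(res$transform, clouds[[pr[1]]])
    reports[[lab]] <- trimmed_metrics(moved, clouds[[pr[2]]],
                                      pms = config$pms, names = pr)
  }
  structure(list(clouds = clouds, reports = reports, icp = icps,
                 scene = scene, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(report_table(x$reports), digits = 3)
  invisible(x)
}

#' Write a pipeline evaluation report to JSON (+ CSV table)
#'
#' @param result a `pipeline_result`.
#' @param path output JSON path; a CSV with the metric table is written
#'   alongside with extension `.csv`.
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  rep <- list(
    config = unclass(result$config),
    metrics = lapply(result$reports, function(r)
      lapply(r$per_pm, function(x) list(hd = x$hd, mad = x$mad))),
    icp = lapply(result$icp, function(r)
      list(iterations = r$iterations, converged = r$converged,
           rmse_history = r$rmse_history)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  write.csv(report_table(result$reports),
            sub("\\.json$", ".csv", path), row.names = FALSE)
  invisible(path)
}
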