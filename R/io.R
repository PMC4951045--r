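# File formats: PLY / XYZ point clouds, JSON transforms and intrinsics,
# NRRD volumes, a flat binary depth-frame container, chessboard CSV.

#' Write a point cloud to PLY
#'
#' Properties `x,y,z` plus `amplitude` and `confidence` when present, all
#' float32.  `format = "binary"` writes binary-little-endian PLY.
#'
#' @param cloud a `point_cloud`.
#' @param path output file.
#' @param format `"ascii"` (default) or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, format = c("ascii", "binary")) {
  format <- match.arg(format)
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  props <- c("x", "y", "z")
  dat <- cloud$points
  if (!is.null(cloud$amplitude)) { props <- c(props, "amplitude"); dat <- cbind(dat, cloud$amplitude) }
  if (!is.null(cloud$confidence)) { props <- c(props, "confidence"); dat <- cbind(dat, cloud$confidence) }
  hdr <- c("ply",
           if (format == "ascii") "format ascii 1.0"
           else "format binary_little_endian 1.0",
           sprintf("comment frame %s", cloud$frame),
           sprintf("element vertex %d", n),
           sprintf("property float %s", props),
           "end_header")
  if (format == "ascii") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(signif(dat, 9), 1, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(t(dat)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a point cloud from PLY or whitespace XYZ
#'
#' Understands ascii and binary-little-endian PLY with float32/float64
#' vertex properties; files without a PLY header are parsed as plain
#' whitespace-separated `x y z` rows.
#'
#' @param path input file.
#' @param frame frame label to attach (overridden by a `comment frame`
#'   header line if present).
#' @return A `point_cloud`.
#' @export
read_ply <- function(path, frame = "G") {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (!identical(first, "ply")) {
    tab <- read.table(path)
    if (ncol(tab) < 3) stop("read_ply: expected at least 3 columns")
    return(point_cloud(as.matrix(tab[, 1:3]), frame = frame))
  }
  fmt <- NULL; n <- NULL; props <- character(0); sizes <- integer(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) stop("read_ply: truncated header")
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "comment" && length(tok) >= 3 && tok[2] == "frame")
      frame <- tok[3]
    else if (tok[1] == "element" && tok[2] == "vertex") n <- as.integer(tok[3])
    else if (tok[1] == "property" && !is.null(n)) {
      props <- c(props, tok[3])
      sizes <- c(sizes, if (tok[2] %in% c("double", "float64")) 8L else 4L)
    } else if (tok[1] == "end_header") break
  }
  if (is.null(n) || !all(c("x", "y", "z") %in% props))
    stop("read_ply: missing vertex element or x/y/z properties")
  p <- length(props)
  if (fmt == "ascii") {
    vals <- scan(con, what = numeric(), n = n * p, quiet = TRUE)
    dat <- matrix(vals, n, p, byrow = TRUE)
  } else if (fmt == "binary_little_endian") {
    if (length(unique(sizes)) == 1) {
      vals <- readBin(con, numeric(), n = n * p, size = sizes[1],
                      endian = "little")
      dat <- matrix(vals, n, p, byrow = TRUE)
    } else {
      dat <- matrix(0, n, p)
      for (i in seq_len(n)) for (j in seq_len(p))
        dat[i, j] <- readBin(con, numeric(), 1, size = sizes[j],
                             endian = "little")
    }
  } else stop("read_ply: unsupported format ", fmt)
  colnames(dat) <- props
  point_cloud(dat[, c("x", "y", "z"), drop = FALSE], frame = frame,
              amplitude = if ("amplitude" %in% props) dat[, "amplitude"],
              confidence = if ("confidence" %in% props) dat[, "confidence"])
}

#' Serialize a rigid transform to JSON
#' @param T a `rigid_transform`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(T, path) {
  stopifnot(inherits(T, "rigid_transform"))
  jsonlite::write_json(
    list(rotation = as.numeric(t(T$rotation)),  # row-major
         translation = T$translation,
         frame_from = T$frame_from, frame_to = T$frame_to),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path input file.
#' @return A `rigid_transform`.
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation,
                  x$frame_from, x$frame_to)
}

#' Serialize camera intrinsics to JSON
#' @param intr a `camera_intrinsics`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intrinsics_json <- function(intr, path) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  jsonlite::write_json(
    list(fx = intr$fx, fy = intr$fy, cx = intr$cx, cy = intr$cy,
         dist = intr$dist, width = intr$width, height = intr$height),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read camera intrinsics from JSON
#' @param path input file.
#' @return A `camera_intrinsics`.
#' @export
read_intrinsics_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_intrinsics(x$fx, x$fy, x$cx, x$cy, x$dist, x$width, x$height)
}

#' Write a volume as NRRD (raw little-endian doubles)
#' @param volume a `ct_volume`.
#' @param path output file (`.nrrd`).
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("NRRD0004",
               "type: double",
               "dimension: 3",
               sprintf("sizes: %s", paste(dim(volume$data), collapse = " ")),
               "encoding: raw",
               "endian: little",
               sprintf("spacings: %s", paste(volume$spacing, collapse = " ")),
               sprintf("axis mins: %s", paste(volume$origin, collapse = " ")),
               ""), con)
  writeBin(as.numeric(volume$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a volume from NRRD (raw encoding)
#' @param path input file.
#' @return A `ct_volume`.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD")) stop("read_nrrd: not an NRRD file")
  sizes <- NULL; spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  type <- "double"
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || ln == "") break
    kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    val <- kv[2]
    switch(kv[1],
           "sizes" = sizes <- as.integer(strsplit(val, " ")[[1]]),
           "spacings" = spacing <- as.numeric(strsplit(val, " ")[[1]]),
           "axis mins" = origin <- as.numeric(strsplit(val, " ")[[1]]),
           "type" = type <- val,
           "encoding" = if (val != "raw") stop("read_nrrd: only raw encoding"))
  }
  if (is.null(sizes) || length(sizes) != 3) stop("read_nrrd: bad sizes")
  sz <- switch(type, "double" = 8L, "float" = 4L, "short" = 2L,
               stop("read_nrrd: unsupported type ", type))
  what <- if (type == "short") integer() else numeric()
  vals <- readBin(con, what, n = prod(sizes), size = sz, endian = "little")
  ct_volume(array(as.numeric(vals), sizes), spacing, origin)
}

#' Write a depth frame as a JSON-header + raw float container
#'
#' Single file: one JSON header line (dimensions and array order), then the
#' xyz, amplitude, confidence and valid arrays as little-endian float32.
#'
#' @param frame a `depth_frame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_depth_frame <- function(frame, path) {
  stopifnot(inherits(frame, "depth_frame"))
  hw <- dim(frame$amplitude)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(height = hw[1], width = hw[2],
                                   arrays = c("xyz", "amplitude",
                                              "confidence", "valid")),
                              auto_unbox = TRUE), con)
  writeBin(as.numeric(frame$xyz), con, size = 4, endian = "little")
  writeBin(as.numeric(frame$amplitude), con, size = 4, endian = "little")
  writeBin(as.numeric(frame$confidence), con, size = 4, endian = "little")
  writeBin(as.numeric(frame$valid), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a depth frame written by [write_depth_frame()]
#' @param path input file.
#' @return A `depth_frame`.
#' @export
read_depth_frame <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(readLines(con, n = 1))
  h <- hdr$height; w <- hdr$width
  rd <- function(n) readBin(con, numeric(), n, size = 4, endian = "little")
  xyz <- array(rd(3 * h * w), c(h, w, 3))
  amp <- matrix(rd(h * w), h, w)
  conf <- matrix(pmin(pmax(rd(h * w), 0), 1), h, w)
  valid <- matrix(rd(h * w) != 0, h, w)
  depth_frame(xyz, amp, conf, valid)
}

#' Export the valid pixels of a depth frame as CSV
#'
#' Columns `u,v,x,y,z,amplitude,confidence`, one row per valid pixel.
#'
#' @param frame a `depth_frame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_depth_frame_csv <- function(frame, path) {
  stopifnot(inherits(frame, "depth_frame"))
  hw <- dim(frame$amplitude)
  idx <- which(frame$valid)
  v <- (idx - 1) %% hw[1]
  u <- (idx - 1) %/% hw[1]
  xyz <- matrix(frame$xyz, prod(hw), 3)
  write.csv(data.frame(u = u, v = v, x = xyz[idx, 1], y = xyz[idx, 2],
                       z = xyz[idx, 3], amplitude = frame$amplitude[idx],
                       confidence = frame$confidence[idx]),
            path, row.names = FALSE)
  invisible(path)
}

#' Write chessboard observations to CSV (+ JSON sidecar)
#'
#' CSV columns `id,X,Y,Z,u,v` (mm, px); the sidecar `<path>.json` records
#' `board_shape` and `square_size`.
#'
#' @param obs a `chessboard_observation`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_chessboard_csv <- function(obs, path) {
  stopifnot(inherits(obs, "chessboard_observation"))
  p <- obs$corners_3d$points
  write.csv(data.frame(id = seq_len(nrow(p)) - 1, X = p[, 1], Y = p[, 2],
                       Z = p[, 3], u = obs$corners_2d[, 1],
                       v = obs$corners_2d[, 2]),
            path, row.names = FALSE)
  jsonlite::write_json(list(board_shape = obs$board_shape,
                            square_size = obs$square_size,
                            frame = obs$corners_3d$frame),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read chessboard observations from CSV (+ JSON sidecar)
#' @param path input CSV file (sidecar `<path>.json` must exist).
#' @return A `chessboard_observation`.
#' @export
read_chessboard_csv <- function(path) {
  tab <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  chessboard_observation(
    point_cloud(as.matrix(tab[, c("X", "Y", "Z")]), frame = side$frame),
    as.matrix(tab[, c("u", "v")]),
    board_shape = side$board_shape, square_size = as.numeric(side$square_size),
    planar_tol = 1e-3)
}
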