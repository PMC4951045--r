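Package: surfreg
Title: Multi-Sensor Rigid Surface Registration for CT, Time-of-Flight and
    Optical-Tracker Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for aligning surfaces of the same physical object acquired
    by three different sensors: a pre-operative CT-like scalar volume, a
    time-of-flight (ToF) depth camera, and a tracked stylus sampling points in
    an optical navigation system's global frame.  Provides frame-aware rigid
    transform algebra, a pinhole camera model with Zhang-style intrinsic
    calibration and Perspective-n-Point pose estimation, Otsu/morphology CT
    surface extraction, confidence-weighted fuzzy c-means depth segmentation,
    trimmed point-to-point iterative closest point (ICP) registration, and
    percentile-trimmed directed Hausdorff / mean absolute distance evaluation.
    A deterministic synthetic-scene simulator (parametric phantoms, ray-cast
    depth frames with flying pixels, stylus sweeps, CT voxelization,
    chessboard calibration views) supplies ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
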