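#' Pinhole camera intrinsics
#'
#' Bundles the left-camera pinhole parameters of a rectified stereo rig:
#' focal lengths and principal point in pixels, plus the image extent.
#' Pixel coordinates are continuous, origin at the top-left corner, x to
#' the right, y down, pixel centers at integer coordinates; this convention
#' is used everywhere in the package, including annotation I/O.
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param u0,v0 principal point (column, row) in pixels.
#' @param width,height image extent in pixels (positive integers).
#' @return an object of class `camera_intrinsics`.
#' @examples
#' K <- camera_intrinsics(fx = 1400, fy = 1400, u0 = 960, v0 = 540,
#'                        width = 1920, height = 1080)
#' @export
camera_intrinsics <- function(fx, fy, u0, v0, width, height) {
  check_finite(c(fx, fy, u0, v0, width, height), "camera intrinsics")
  if (fx <= 0 || fy <= 0) stopf("focal lengths must be positive", class = "config_error")
  if (width <= 0 || height <= 0 || width != round(width) || height != round(height))
    stopf("width and height must be positive integers", class = "config_error")
  structure(list(fx = fx, fy = fy, u0 = u0, v0 = v0,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("Pinhole intrinsics: fx=%.6g fy=%.6g principal=(%.6g, %.6g) %dx%d px\n",
              x$fx, x$fy, x$u0, x$v0, x$width, x$height))
  invisible(x)
}

#' Stereo rig extrinsics
#'
#' Rotation and translation taking left-camera coordinates into the second
#' camera's frame. For a rectified horizontal rig `R` is the identity and
#' `T = (-baseline, 0, 0)` meters, so that left/right disparity is
#' `fx * baseline / Z`.
#'
#' @param baseline_m baseline in meters (> 0).
#' @param R 3x3 rotation matrix, orthonormal with determinant +1.
#' @param T length-3 translation in meters; defaults to the rectified
#'   horizontal layout `c(-baseline_m, 0, 0)`.
#' @return an object of class `stereo_extrinsics`.
#' @export
stereo_extrinsics <- function(baseline_m, R = diag(3), T = c(-baseline_m, 0, 0)) {
  if (!is.numeric(baseline_m) || baseline_m <= 0)
    stopf("baseline_m must be positive", class = "config_error")
  R <- matrix(as.numeric(R), 3, 3)
  check_finite(R, "rotation matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stopf("R must be orthonormal with determinant +1", class = "config_error")
  T <- as.numeric(T)
  if (length(T) != 3) stopf("T must have length 3", class = "config_error")
  structure(list(R = R, T = T, baseline_m = baseline_m),
            class = "stereo_extrinsics")
}

identity_extrinsics <- function() stereo_extrinsics(1e-12, T = c(0, 0, 0))

#' Read a stereo calibration file
#'
#' Reads YAML or JSON with keys `fx, fy, u0, v0, width, height, baseline_m`
#' and optional `R` (row-major, 9 floats) and `T` (3 floats, meters). A
#' `units` key other than "pixels+meters" is rejected, and the presence of
#' distortion coefficients triggers a warning: the package assumes rectified,
#' undistorted images.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return list with elements `intrinsics` (camera_intrinsics) and
#'   `extrinsics` (stereo_extrinsics or NULL when no baseline is given).
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stopf("calibration file not found: %s", path, class = "io_error")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    stopf("unsupported calibration format: .%s", ext, class = "io_error"))
  if (!is.null(raw$units) && !identical(raw$units, "pixels+meters"))
    stopf("unknown calibration units '%s' (expected 'pixels+meters')",
          raw$units, class = "io_error")
  need <- c("fx", "fy", "u0", "v0", "width", "height")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stopf("calibration missing keys: %s", paste(miss, collapse = ", "),
                          class = "io_error")
  if (any(c("dist", "distortion", "k1", "k2", "p1", "p2") %in% names(raw)))
    warnf("calibration file carries distortion coefficients; stereofish assumes rectified, undistorted images and ignores them")
  K <- camera_intrinsics(raw$fx, raw$fy, raw$u0, raw$v0, raw$width, raw$height)
  E <- NULL
  if (!is.null(raw$baseline_m)) {
    R <- if (is.null(raw$R)) diag(3) else matrix(as.numeric(raw$R), 3, 3, byrow = TRUE)
    T <- if (is.null(raw$T)) c(-raw$baseline_m, 0, 0) else as.numeric(raw$T)
    E <- stereo_extrinsics(raw$baseline_m, R = R, T = T)
  }
  list(intrinsics = K, extrinsics = E)
}

#' Write a stereo calibration file
#'
#' @param K camera_intrinsics.
#' @param E stereo_extrinsics or NULL.
#' @param path output path (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_calibration <- function(K, E = NULL, path) {
  x <- list(units = "pixels+meters", fx = K$fx, fy = K$fy, u0 = K$u0, v0 = K$v0,
            width = K$width, height = K$height)
  if (!is.null(E)) {
    x$baseline_m <- E$baseline_m
    x$R <- as.numeric(t(E$R))
    x$T <- E$T
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    stopf("unsupported calibration format: .%s", ext, class = "io_error"))
  invisible(path)
}
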