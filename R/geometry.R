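#' Back-project image keypoints to 3D
#'
#' Inverts the pinhole projection for rectified left-image keypoints with
#' known depth: `X = (u - u0) * z / fx`, `Y = (v - v0) * z / fy`, `Z = z`,
#' in the left-camera frame (Z along the optical axis). Reconstruction is
#' always expressed in the left-camera frame; extrinsics enter only when
#' projecting into the second camera with [project()].
#'
#' @param u,v pixel coordinates (vectors of equal length).
#' @param depth_m depth from the camera plane in meters (> 0).
#' @param K [camera_intrinsics()].
#' @return an n x 3 matrix with columns X, Y, Z (meters).
#' @examples
#' K <- camera_intrinsics(700, 700, 960, 540, 1920, 1080)
#' back_project(1100, 540, 2, K)   # (0.4, 0, 2)
#' @export
back_project <- function(u, v, depth_m, K) {
  stopifnot(inherits(K, "camera_intrinsics"))
  n <- length(u)
  if (length(v) != n || length(depth_m) != n)
    stopf("u, v, depth_m must have equal length", class = "domain_error")
  check_finite(c(u, v), "pixel coordinates")
  if (any(!is.finite(depth_m)) || any(depth_m <= 0))
    stopf("depth must be present, finite and positive", class = "invalid_depth_error")
  cbind(X = (u - K$u0) * depth_m / K$fx,
        Y = (v - K$v0) * depth_m / K$fy,
        Z = depth_m)
}

#' Project 3D points into a camera
#'
#' Forward pinhole projection. Points given in the left-camera frame are
#' first moved into the target camera's frame with `R %*% p + T` when
#' extrinsics are supplied; for the left camera itself use `E = NULL`.
#'
#' @param p n x 3 matrix (or length-3 vector) of points, meters, left-camera
#'   frame.
#' @param K [camera_intrinsics()].
#' @param E [stereo_extrinsics()] for the target camera, or NULL for identity.
#' @return data.frame with columns `u`, `v` (pixels) and `depth_m` (meters,
#'   depth in the target camera's frame).
#' @export
project <- function(p, K, E = NULL) {
  stopifnot(inherits(K, "camera_intrinsics"))
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  check_finite(p, "3D points")
  q <- p
  if (!is.null(E)) {
    stopifnot(inherits(E, "stereo_extrinsics"))
    q <- sweep(p %*% t(E$R), 2, -E$T)
  }
  if (any(q[, 3] <= 0))
    stopf("point behind the camera (Z' <= 0)", class = "behind_camera_error")
  data.frame(u = K$fx * q[, 1] / q[, 3] + K$u0,
             v = K$fy * q[, 2] / q[, 3] + K$v0,
             depth_m = q[, 3])
}

#' Convert stereo disparity to depth
#'
#' For a rectified rig, `depth = fx * baseline / disparity`.
#'
#' @param d disparity in pixels (> 0); vectorized.
#' @param fx focal length in pixels.
#' @param baseline_m rig baseline in meters.
#' @return depth in meters.
#' @examples
#' disparity_to_depth(42, fx = 700, baseline_m = 0.12)  # 2 m
#' @export
disparity_to_depth <- function(d, fx, baseline_m) {
  if (any(!is.finite(d)) || any(d <= 0))
    stopf("disparity must be finite and positive", class = "invalid_disparity_error")
  fx * baseline_m / d
}

#' Sample a depth raster at keypoint locations
#'
#' The nearest-pixel value, or the median over a k x k window centered on
#' the nearest pixel (NA/non-positive entries excluded). Whether a detector
#' pipeline reads depth at the exact pixel or pools a neighborhood is a
#' deployment choice; both are exposed, default nearest pixel (k = 1).
#'
#' @param raster numeric matrix, rows = image rows (v), cols = image columns
#'   (u); either depth in meters or disparity in pixels.
#' @param u,v continuous pixel coordinates.
#' @param window odd window side k (default 1 = nearest pixel).
#' @return numeric vector of sampled values; NA where no valid sample exists.
#' @export
depth_at <- function(raster, u, v, window = 1) {
  stopifnot(is.matrix(raster))
  if (window < 1 || window %% 2 != 1)
    stopf("window must be a positive odd integer", class = "config_error")
  h <- nrow(raster); w <- ncol(raster); k <- (window - 1) / 2
  vapply(seq_along(u), function(i) {
    ci <- round(u[i]) + 1L; ri <- round(v[i]) + 1L  # pixel centers at integers
    rows <- max(1L, ri - k):min(h, ri + k)
    cols <- max(1L, ci - k):min(w, ci + k)
    if (ri < 1L || ri > h || ci < 1L || ci > w) return(NA_real_)
    vals <- raster[rows, cols]
    vals <- vals[is.finite(vals) & vals > 0]
    if (!length(vals)) NA_real_ else stats::median(vals)
  }, numeric(1))
}
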