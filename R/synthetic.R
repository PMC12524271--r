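# Ground-truthed synthetic stereo keypoint scenes.
#
# The generator emulates the acquisition geometry of a small-tank stereo
# rig: a rectified 1920x1080 pair with a 120 mm baseline, grass carp of
# four size classes swimming freely at 0.5-2.5 m, each fish reduced to its
# four anatomical keypoints on a circular-arc midline (the simplest shape
# exhibiting the chord-vs-arc length error of a bent body). Environmental
# condition presets (clear/turbid water, low/high density, low light) are
# realized as keypoint jitter, relative depth noise, keypoint dropout and
# false-positive detections. It produces annotations and depth, not pixels.

#' Default synthetic camera rig
#'
#' A rectified 1920x1080 stereo pair with a 120 mm baseline and a focal
#' length of 1050 px, representative of a consumer stereo depth camera at
#' full HD.
#'
#' @return list with `intrinsics` and `extrinsics`.
#' @export
default_rig <- function() {
  list(intrinsics = camera_intrinsics(1050, 1050, 960, 540, 1920, 1080),
       extrinsics = stereo_extrinsics(0.12))
}

#' Environmental condition presets
#'
#' Noise levels standing in for the five acquisition strata, ordered by
#' severity. Values are generator-side conventions (jitter sigma in px,
#' relative depth noise, per-keypoint dropout probability, false positives
#' per true fish), documented here and fully overridable.
#'
#' @return named list of noise parameter lists.
#' @export
condition_presets <- function() {
  list(
    "clear-low"   = list(kp_jitter_px = 0.3, depth_rel_sd = 0.001,
                         dropout_p = 0.00, false_positive_rate = 0.00),
    "clear-high"  = list(kp_jitter_px = 0.5, depth_rel_sd = 0.002,
                         dropout_p = 0.02, false_positive_rate = 0.01),
    "turbid-low"  = list(kp_jitter_px = 0.8, depth_rel_sd = 0.004,
                         dropout_p = 0.04, false_positive_rate = 0.02),
    "turbid-high" = list(kp_jitter_px = 1.2, depth_rel_sd = 0.007,
                         dropout_p = 0.07, false_positive_rate = 0.03),
    "low-light"   = list(kp_jitter_px = 1.5, depth_rel_sd = 0.010,
                         dropout_p = 0.10, false_positive_rate = 0.05))
}

# size-class length ranges (cm), seeded from the packaged real measurements
CLASS_RANGES <- list("L" = c(16.9, 18.6), "M-L" = c(13.1, 15.5),
                     "M-S" = c(10.0, 12.4), "S" = c(8.1, 9.1))

#' Sample a synthetic fish population
#'
#' Lengths uniform within the size-class range; width drawn as
#' `length * ratio` with `ratio ~ Normal(0.225, 0.015)` (the width/length
#' ratios of the packaged measurements scatter around 0.22); mass from the
#' allometric power law `a * length^b * exp(eps)`, `eps ~ Normal(0, noise_sd)`.
#'
#' @param n number of fish.
#' @param class_mix named probabilities over `L, M-L, M-S, S` (sum 1).
#' @param seed integer seed; the population is deterministic given it.
#' @param allometry list with `a`, `b`, `noise_sd` (defaults 0.018, 3, 0.1,
#'   grams from centimeters).
#' @return data.frame: `fish_id`, `size_class`, `true_length_cm`,
#'   `true_width_cm`, `true_mass_g`.
#' @export
sample_population <- function(n, class_mix = c("L" = 0.25, "M-L" = 0.25,
                                               "M-S" = 0.25, "S" = 0.25),
                              seed = 1,
                              allometry = list(a = 0.018, b = 3, noise_sd = 0.1)) {
  if (n < 0) stopf("n must be >= 0", class = "config_error")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% names(CLASS_RANGES)) ||
      any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-9)
    stopf("class_mix must be named probabilities over %s summing to 1",
          paste(names(CLASS_RANGES), collapse = ", "), class = "config_error")
  if (n == 0)
    return(data.frame(fish_id = character(), size_class = character(),
                      true_length_cm = numeric(), true_width_cm = numeric(),
                      true_mass_g = numeric(), stringsAsFactors = FALSE))
  with_seed(substream_seed(seed, "population"), {
    cls <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
    len <- vapply(cls, function(cl)
      stats::runif(1, CLASS_RANGES[[cl]][1], CLASS_RANGES[[cl]][2]), numeric(1))
    ratio <- pmax(0.12, stats::rnorm(n, 0.225, 0.015))
    wid <- len * ratio
    mass <- allometry$a * len^allometry$b *
      exp(stats::rnorm(n, 0, allometry$noise_sd))
    data.frame(fish_id = sprintf("fish%03d", seq_len(n)), size_class = cls,
               true_length_cm = len, true_width_cm = wid, true_mass_g = mass,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Sample free-swimming poses
#'
#' Centroids placed so they project inside the left image at a depth
#' uniform in `depth_range`; orientation limited to modest deviations from
#' the image plane (annotation practice keeps near-parallel fish only);
#' body bend `~ |Normal(0, bend_sd)|` in 1/m, capped so the arc does not
#' self-intersect.
#'
#' @param specs population from [sample_population()].
#' @param seed integer seed.
#' @param depth_range camera-distance range in meters.
#' @param bend_sd standard deviation of the half-normal bend curvature
#'   (1/m); 0 gives straight fish.
#' @param max_tilt maximum |yaw| and |pitch| in radians (default 0.3).
#' @param K intrinsics used to keep centroids in frame.
#' @return data.frame of poses, one row per fish.
#' @export
sample_poses <- function(specs, seed = 1, depth_range = c(0.5, 2.5),
                         bend_sd = 0.5, max_tilt = 0.3, K = default_rig()$intrinsics) {
  n <- nrow(specs)
  with_seed(substream_seed(seed, "pose"), {
    z <- stats::runif(n, depth_range[1], depth_range[2])
    u <- stats::runif(n, 0.15 * K$width, 0.85 * K$width)
    v <- stats::runif(n, 0.15 * K$height, 0.85 * K$height)
    len_m <- specs$true_length_cm / 100
    bend <- abs(stats::rnorm(n, 0, bend_sd)) * sample(c(-1, 1), n, replace = TRUE)
    cap <- (pi - 1e-6) / len_m  # |bend| * length < pi
    bend <- pmax(pmin(bend, cap), -cap)
    data.frame(fish_id = specs$fish_id,
               cx = (u - K$u0) * z / K$fx, cy = (v - K$v0) * z / K$fy, cz = z,
               yaw = stats::runif(n, -max_tilt, max_tilt),
               pitch = stats::runif(n, -max_tilt, max_tilt),
               roll = stats::runif(n, -pi, pi),
               bend = bend, stringsAsFactors = FALSE)
  })
}

euler_rotation <- function(yaw, pitch, roll) {
  cy <- cos(yaw); sy <- sin(yaw)
  cp <- cos(pitch); sp <- sin(pitch)
  cr <- cos(roll); sr <- sin(roll)
  Rz <- matrix(c(cr, -sr, 0, sr, cr, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cp, -sp, 0, sp, cp), 3, 3, byrow = TRUE)
  Ry %*% Rx %*% Rz
}

# 3D keypoints of one fish in its local frame: midline is a circular arc of
# arc length `len` and curvature `bend` in the x-y (sagittal) plane, head at
# arc end +len/2, tail at -len/2, width points offset +/- wid/2 along the
# midline normal at mid-body.
fish_keypoints_local <- function(len, wid, bend) {
  arc_point <- function(t) {
    if (abs(bend) < 1e-9) c(t, 0, 0)
    else { R <- 1 / bend; c(R * sin(t / R), R * (1 - cos(t / R)), 0) }
  }
  rbind(head = arc_point(len / 2), tail = arc_point(-len / 2),
        top = c(0, wid / 2, 0), bottom = c(0, -wid / 2, 0))
}

#' Render a stereo keypoint scene
#'
#' Places each fish's four keypoints in 3D from its spec and pose, projects
#' them into the rectified left and right cameras and assembles the ground
#' truth bundle every downstream stage consumes. The head-tail chord of a
#' bent fish is strictly shorter than its true (arc) length; at `bend = 0`
#' they coincide.
#'
#' @param specs population data frame ([sample_population()]).
#' @param poses pose data frame ([sample_poses()]).
#' @param rig list with `intrinsics`, `extrinsics` ([default_rig()]).
#' @param frame_id frame identifier stamped on the observations.
#' @return a `scene_bundle` list: `camera`, `extrinsics`, `fish` (ground
#'   truth incl. chord length and `truncated` flag), `kp3d` (named list of
#'   4 x 3 matrices), `left`/`right` observation data frames with true
#'   depths, `boxes` (left-image boxes), `disparity` (per keypoint).
#' @export
render_scene <- function(specs, poses, rig = default_rig(), frame_id = "frame1") {
  K <- rig$intrinsics; E <- rig$extrinsics
  stopifnot(nrow(specs) == nrow(poses))
  kp3d <- list()
  left_l <- right_l <- box_l <- vector("list", nrow(specs))
  fish <- merge(specs, poses, by = "fish_id", sort = FALSE)
  fish$chord_length_m <- rep(NA_real_, nrow(fish))
  fish$truncated <- rep(FALSE, nrow(fish))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]; po <- poses[poses$fish_id == sp$fish_id, ]
    loc <- fish_keypoints_local(sp$true_length_cm / 100, sp$true_width_cm / 100,
                                po$bend)
    R <- euler_rotation(po$yaw, po$pitch, po$roll)
    pts <- loc %*% t(R)
    pts <- sweep(pts, 2, -c(po$cx, po$cy, po$cz))
    rownames(pts) <- rownames(loc)
    if (any(pts[, 3] <= 0))
      stopf("fish %s behind camera", sp$fish_id, class = "placement_error")
    kp3d[[sp$fish_id]] <- pts
    pl <- project(pts, K)
    pr <- project(pts, K, E)
    inside <- function(p) all(p$u >= 0 & p$u < K$width & p$v >= 0 & p$v < K$height)
    fish$truncated[i] <- !(inside(pl) && inside(pr))
    fish$chord_length_m[i] <- sqrt(sum((pts["head", ] - pts["tail", ])^2))
    obs <- function(p) data.frame(frame_id = frame_id, fish_id = sp$fish_id,
                                  keypoint = rownames(pts), u = p$u, v = p$v,
                                  visible = TRUE, depth_m = p$depth_m, score = 1,
                                  stringsAsFactors = FALSE)
    left_l[[i]] <- obs(pl); right_l[[i]] <- obs(pr)
    pad_u <- 0.1 * diff(range(pl$u)) + 2; pad_v <- 0.1 * diff(range(pl$v)) + 2
    box_l[[i]] <- data.frame(frame_id = frame_id, fish_id = sp$fish_id,
                             x_min = min(pl$u) - pad_u, y_min = min(pl$v) - pad_v,
                             x_max = max(pl$u) + pad_u, y_max = max(pl$v) + pad_v,
                             score = 1, stringsAsFactors = FALSE)
  }
  left <- if (length(left_l)) do.call(rbind, left_l) else empty_observations()
  right <- if (length(right_l)) do.call(rbind, right_l) else empty_observations()
  boxes <- if (length(box_l)) do.call(rbind, box_l) else empty_boxes()
  disparity <- data.frame(fish_id = left$fish_id, keypoint = left$keypoint,
                          d = left$u - right$u, stringsAsFactors = FALSE)
  structure(list(camera = K, extrinsics = E, fish = fish, kp3d = kp3d,
                 left = left, right = right,
                 boxes = boxes, disparity = disparity,
                 frame_id = frame_id),
            class = "scene_bundle")
}

#' @export
print.scene_bundle <- function(x, ...) {
  cat(sprintf("Synthetic stereo scene: %d fish (%d truncated), %dx%d px, baseline %.0f mm\n",
              nrow(x$fish), sum(x$fish$truncated), x$camera$width,
              x$camera$height, x$extrinsics$baseline_m * 1000))
  invisible(x)
}

#' Corrupt a rendered scene into a realistic detection set
#'
#' Applies, in order: Gaussian pixel jitter to keypoint coordinates,
#' multiplicative depth noise `z * (1 + Normal(0, depth_rel_sd))`,
#' per-keypoint dropout (visibility lost with probability `dropout_p`), and
#' Poisson false-positive fish at `false_positive_rate` per true fish.
#' Deterministic given the seed; all-zero noise returns the observations
#' unchanged.
#'
#' @param bundle a [render_scene()] bundle.
#' @param noise list with `kp_jitter_px`, `depth_rel_sd`, `dropout_p`,
#'   `false_positive_rate`; or a preset name from [condition_presets()].
#' @param seed integer seed.
#' @return list with `observations` and `boxes` data frames (detections on
#'   the left image, scores included).
#' @export
corrupt <- function(bundle, noise = "clear-low", seed = 1) {
  if (is.character(noise)) {
    presets <- condition_presets()
    if (!noise %in% names(presets))
      stopf("unknown condition preset '%s'", noise, class = "config_error")
    noise <- presets[[noise]]
  }
  if (any(unlist(noise) < 0)) stopf("noise parameters must be >= 0", class = "config_error")
  obs <- bundle$left
  boxes <- bundle$boxes
  with_seed(substream_seed(seed, "noise"), {
    n <- nrow(obs)
    if (noise$kp_jitter_px > 0) {
      obs$u <- obs$u + stats::rnorm(n, 0, noise$kp_jitter_px)
      obs$v <- obs$v + stats::rnorm(n, 0, noise$kp_jitter_px)
    }
    if (noise$depth_rel_sd > 0)
      obs$depth_m <- obs$depth_m * (1 + stats::rnorm(n, 0, noise$depth_rel_sd))
    if (noise$dropout_p > 0)
      obs$visible <- obs$visible & (stats::runif(n) >= noise$dropout_p)
    if (noise$dropout_p >= 1) obs$visible <- FALSE
    obs$score <- rep(stats::runif(nrow(bundle$fish), 0.7, 1),
                     each = 4)[seq_len(n)]
    boxes$score <- obs$score[match(boxes$fish_id, obs$fish_id)]
    n_fp <- if (noise$false_positive_rate > 0)
      stats::rpois(1, noise$false_positive_rate * nrow(bundle$fish)) else 0L
    if (n_fp > 0) {
      K <- bundle$camera
      for (j in seq_len(n_fp)) {
        cu <- stats::runif(1, 0.1, 0.9) * K$width
        cv <- stats::runif(1, 0.1, 0.9) * K$height
        span <- stats::runif(1, 30, 120)
        fid <- sprintf("fp%03d", j)
        sc <- stats::runif(1, 0.1, 0.8)
        obs <- rbind(obs, data.frame(
          frame_id = bundle$frame_id, fish_id = fid,
          keypoint = FISH_KEYPOINTS,
          u = cu + stats::rnorm(4, 0, span / 2),
          v = cv + stats::rnorm(4, 0, span / 4),
          visible = TRUE,
          depth_m = stats::runif(1, 0.5, 2.5) * (1 + stats::rnorm(4, 0, 0.02)),
          score = sc, stringsAsFactors = FALSE))
        boxes <- rbind(boxes, data.frame(
          frame_id = bundle$frame_id, fish_id = fid,
          x_min = cu - span, y_min = cv - span / 2,
          x_max = cu + span, y_max = cv + span / 2,
          score = sc, stringsAsFactors = FALSE))
      }
    }
  })
  list(observations = obs, boxes = boxes)
}

#' Simulate a full scene in one call
#'
#' Population, poses, rendering and corruption driven by one config, all
#' randomness derived from `seed` via named substreams.
#'
#' @param n_fish number of fish.
#' @param condition preset name (see [condition_presets()]) or noise list.
#' @param seed master seed.
#' @param class_mix forwarded to [sample_population()].
#' @param bend_sd forwarded to [sample_poses()].
#' @param rig camera rig.
#' @return list with `bundle` (ground truth) and `detections` (corrupted).
#' @export
simulate_scene <- function(n_fish, condition = "clear-low", seed = 1,
                           class_mix = c("L" = 0.25, "M-L" = 0.25,
                                         "M-S" = 0.25, "S" = 0.25),
                           bend_sd = 0.5, rig = default_rig()) {
  specs <- sample_population(n_fish, class_mix, seed = seed)
  poses <- sample_poses(specs, seed = seed, bend_sd = bend_sd,
                        K = rig$intrinsics)
  bundle <- render_scene(specs, poses, rig = rig)
  detections <- corrupt(bundle, noise = condition, seed = seed)
  list(bundle = bundle, detections = detections)
}

#' Write a synthetic dataset to disk
#'
#' Emits COCO-keypoint JSON and YOLO-pose labels for the left-image ground
#' truth, a PFM depth raster (true keypoint depths splatted at their
#' pixels, background 0), a ground-truth CSV of true sizes and masses, and
#' a manifest JSON recording the camera and every parameter. All files
#' round-trip through the package's own readers.
#'
#' @param bundle a [render_scene()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  K <- bundle$camera
  tryCatch({
    write_coco_keypoints(bundle$left, bundle$boxes,
                         file.path(dir, "annotations.json"), K$width, K$height)
    write_yolo_pose(bundle$left, bundle$boxes,
                    file.path(dir, paste0(bundle$frame_id, ".txt")),
                    K$width, K$height)
    depth <- matrix(0, K$height, K$width)
    vis <- bundle$left$visible
    ri <- round(bundle$left$v[vis]) + 1L; ci <- round(bundle$left$u[vis]) + 1L
    keep <- ri >= 1 & ri <= K$height & ci >= 1 & ci <= K$width
    depth[cbind(ri[keep], ci[keep])] <- bundle$left$depth_m[vis][keep]
    write_pfm(depth, file.path(dir, "depth.pfm"))
    truth <- bundle$fish[, c("fish_id", "size_class", "true_length_cm",
                             "true_width_cm", "true_mass_g", "bend", "truncated")]
    utils::write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
    write_calibration(K, bundle$extrinsics, file.path(dir, "calibration.yaml"))
    jsonlite::write_json(list(format = "stereofish-scene/1",
                              frame_id = bundle$frame_id,
                              n_fish = nrow(bundle$fish),
                              baseline_m = bundle$extrinsics$baseline_m),
                         file.path(dir, "manifest.json"), auto_unbox = TRUE)
  }, error = function(e) stopf("failed writing dataset under %s: %s",
                               dir, conditionMessage(e), class = "io_error"))
  invisible(dir)
}
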