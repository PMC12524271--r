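#' Fish body length and width from reconstructed keypoints
#'
#' Body length is the 3D Euclidean distance between the head and tail
#' keypoints (tail fin excluded by the schema); body width is the distance
#' between the upper-width and lower-width keypoints. No projection onto a
#' body axis is performed — both are raw chord lengths, so on a bent fish
#' the length underestimates the arc length of the midline.
#'
#' @param kp3d a 4 x 3 numeric matrix of points (meters) with rows named
#'   `head`, `tail`, `top`, `bottom` — as produced by [back_project()].
#' @return distance in meters.
#' @examples
#' kp <- rbind(head = c(0, 0, 1), tail = c(0.03, 0.04, 1),
#'             top = c(0, 0.02, 1), bottom = c(0, -0.02, 1))
#' body_length(kp)  # 0.05
#' body_width(kp)   # 0.04
#' @export
body_length <- function(kp3d) point_distance(kp3d, "head", "tail")

#' @rdname body_length
#' @export
body_width <- function(kp3d) point_distance(kp3d, "top", "bottom")

point_distance <- function(kp3d, a, b) {
  if (is.null(rownames(kp3d)) || !all(c(a, b) %in% rownames(kp3d)))
    stopf("keypoint matrix must have rows '%s' and '%s'", a, b, class = "schema_error")
  check_finite(kp3d[c(a, b), ], "keypoint coordinates")
  sqrt(sum((kp3d[a, ] - kp3d[b, ])^2))
}

#' Estimate fish sizes from 2D detections and depth
#'
#' The per-fish pipeline stage: resolves a depth for each visible keypoint
#' (from the observation itself or by sampling a depth raster), back-projects
#' the four keypoints to the left-camera frame, and measures body length and
#' width. Fish that do not present all four keypoints visible with positive
#' depth are skipped, not guessed: the skip reasons are returned in the
#' `skipped` attribute (`reason` one of `invisible_keypoint`,
#' `missing_keypoint`, `unresolved_depth`).
#'
#' @param observations keypoint observation data frame (see
#'   [read_coco_keypoints()] for the layout).
#' @param K [camera_intrinsics()].
#' @param depth depth raster (matrix, meters) consulted for keypoints whose
#'   `depth_m` is NA, or NULL when all depths travel with the observations.
#' @param window depth-sampling window passed to [depth_at()].
#' @param aggregate `"none"` (default) keeps one estimate per frame and fish;
#'   `"mean"` averages repeated frames of the same fish.
#' @return data.frame with `fish_id`, `frame_id`, `length_m`, `width_m`,
#'   `length_cm`, `width_cm`; attribute `skipped` lists excluded fish.
#' @export
estimate_sizes <- function(observations, K, depth = NULL, window = 1,
                           aggregate = c("none", "mean")) {
  aggregate <- match.arg(aggregate)
  check_schema(observations)
  keys <- unique(observations[, c("frame_id", "fish_id")])
  out <- vector("list", nrow(keys))
  skipped <- list()
  for (i in seq_len(nrow(keys))) {
    d <- observations[observations$frame_id == keys$frame_id[i] &
                      observations$fish_id == keys$fish_id[i], ]
    d <- d[match(FISH_KEYPOINTS, d$keypoint), ]
    skip <- function(reason)
      data.frame(fish_id = keys$fish_id[i], frame_id = keys$frame_id[i],
                 reason = reason, stringsAsFactors = FALSE)
    if (any(is.na(d$keypoint)) || anyNA(d$u)) {
      skipped[[length(skipped) + 1]] <- skip("missing_keypoint"); next
    }
    if (!all(d$visible)) {
      skipped[[length(skipped) + 1]] <- skip("invisible_keypoint"); next
    }
    z <- d$depth_m
    if (!is.null(depth) && anyNA(z)) {
      miss <- is.na(z)
      z[miss] <- depth_at(depth, d$u[miss], d$v[miss], window = window)
    }
    if (anyNA(z) || any(z <= 0)) {
      skipped[[length(skipped) + 1]] <- skip("unresolved_depth"); next
    }
    p <- back_project(d$u, d$v, z, K)
    rownames(p) <- d$keypoint
    L <- body_length(p); W <- body_width(p)
    if (W > L)
      warnf("fish %s frame %s: width %.3f m exceeds length %.3f m",
            keys$fish_id[i], keys$frame_id[i], W, L)
    out[[i]] <- data.frame(fish_id = keys$fish_id[i], frame_id = keys$frame_id[i],
                           length_m = L, width_m = W, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out[!vapply(out, is.null, logical(1))])
         else data.frame(fish_id = character(), frame_id = character(),
                         length_m = numeric(), width_m = numeric())
  if (is.null(res)) res <- data.frame(fish_id = character(), frame_id = character(),
                                      length_m = numeric(), width_m = numeric())
  if (aggregate == "mean" && nrow(res)) {
    agg <- stats::aggregate(cbind(length_m, width_m) ~ fish_id, data = res, FUN = mean)
    res <- data.frame(fish_id = agg$fish_id, frame_id = NA_character_,
                      length_m = agg$length_m, width_m = agg$width_m,
                      stringsAsFactors = FALSE)
  }
  res$length_cm <- res$length_m * 100
  res$width_cm <- res$width_m * 100
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else data.frame(fish_id = character(), frame_id = character(),
                                          reason = character())
  res
}

#' Write size estimates to CSV
#'
#' Centimeters, rounded to 2 decimals at this reporting boundary only; the
#' returned objects keep full precision.
#'
#' @param sizes output of [estimate_sizes()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_size_csv <- function(sizes, path) {
  out <- data.frame(fish_id = sizes$fish_id, frame_id = sizes$frame_id,
                    length_cm = round(sizes$length_cm, 2),
                    width_cm = round(sizes$width_cm, 2))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
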