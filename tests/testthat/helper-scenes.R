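# Shared fixtures, built in code.

test_camera <- function() camera_intrinsics(700, 700, 960, 540, 1920, 1080)

zero_noise <- list(kp_jitter_px = 0, depth_rel_sd = 0, dropout_p = 0,
                   false_positive_rate = 0)

# a hand-positioned single fish as a long observation data frame
single_fish_obs <- function(depths = c(2, 2, 2, 2), visible = rep(TRUE, 4)) {
  data.frame(frame_id = "f1", fish_id = "fishA",
             keypoint = fish_keypoint_schema(),
             u = c(900, 1020, 960, 960), v = c(540, 540, 510, 570),
             visible = visible, depth_m = depths, score = 1,
             stringsAsFactors = FALSE)
}

# random detection/truth scene for metric tests: ngt ground truths, their
# perturbed detections plus nfp false positives, random scores
random_metric_scene <- function(ngt, nfp, kp_noise = 8) {
  mk_box <- function(cx, cy, w, h) c(cx - w/2, cy - h/2, cx + w/2, cy + h/2)
  gts <- dets <- list()
  for (g in seq_len(ngt)) {
    cx <- runif(1, 200, 1700); cy <- runif(1, 150, 900)
    w <- runif(1, 80, 250); h <- runif(1, 40, 120)
    kp <- cbind(runif(4, cx - w/2, cx + w/2), runif(4, cy - h/2, cy + h/2))
    vis <- runif(4) > 0.2
    if (!any(vis)) vis[1] <- TRUE
    gts[[g]] <- list(box = mk_box(cx, cy, w, h), kp = kp, vis = vis,
                     area = w * h)
    dets[[length(dets) + 1]] <- list(
      box = mk_box(cx + rnorm(1, 0, 6), cy + rnorm(1, 0, 6), w, h),
      kp = kp + matrix(rnorm(8, 0, kp_noise), 4, 2), score = runif(1))
  }
  for (f in seq_len(nfp)) {
    cx <- runif(1, 200, 1700); cy <- runif(1, 150, 900)
    w <- runif(1, 80, 250); h <- runif(1, 40, 120)
    dets[[length(dets) + 1]] <- list(
      box = mk_box(cx, cy, w, h),
      kp = cbind(runif(4, cx - w/2, cx + w/2), runif(4, cy - h/2, cy + h/2)),
      score = runif(1))
  }
  truths <- data.frame(
    x_min = sapply(gts, function(g) g$box[1]),
    y_min = sapply(gts, function(g) g$box[2]),
    x_max = sapply(gts, function(g) g$box[3]),
    y_max = sapply(gts, function(g) g$box[4]),
    area = sapply(gts, function(g) g$area))
  truths$keypoints <- lapply(gts, function(g) g$kp)
  truths$visible <- lapply(gts, function(g) g$vis)
  detections <- data.frame(
    x_min = sapply(dets, function(d) d$box[1]),
    y_min = sapply(dets, function(d) d$box[2]),
    x_max = sapply(dets, function(d) d$box[3]),
    y_max = sapply(dets, function(d) d$box[4]),
    score = sapply(dets, function(d) d$score))
  detections$keypoints <- lapply(dets, function(d) d$kp)
  list(detections = detections, truths = truths)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}
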