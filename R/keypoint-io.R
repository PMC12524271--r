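# Detection / annotation interchange.
#
# The in-memory currency is a pair of data frames:
#   observations: frame_id, fish_id, keypoint (head|tail|top|bottom),
#                 u, v, visible, depth_m (optional, NA allowed), score
#   boxes:        frame_id, fish_id, x_min, y_min, x_max, y_max, score
# Pixel convention: continuous coordinates, origin top-left, pixel centers
# at integer coordinates (see ?camera_intrinsics).

#' The fixed 4-point fish keypoint schema
#'
#' Head, tail, upper-width and lower-width points; the tail fin is excluded
#' from the length measurement by construction of the schema.
#'
#' @return character vector of keypoint names, in canonical order.
#' @export
fish_keypoint_schema <- function() FISH_KEYPOINTS

empty_observations <- function() {
  data.frame(frame_id = character(), fish_id = character(),
             keypoint = character(), u = numeric(), v = numeric(),
             visible = logical(), depth_m = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

empty_boxes <- function() {
  data.frame(frame_id = character(), fish_id = character(),
             x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

check_schema <- function(obs) {
  bad <- setdiff(unique(obs$keypoint), FISH_KEYPOINTS)
  if (length(bad))
    stopf("unknown keypoints in schema: %s (expected %s)",
          paste(bad, collapse = ", "), paste(FISH_KEYPOINTS, collapse = ", "),
          class = "schema_error")
  invisible(obs)
}

#' Read COCO-keypoint annotations
#'
#' Accepts the COCO keypoint JSON layout with a single fish category whose
#' `keypoints` field names the 4-point schema. Keypoint visibility follows
#' COCO (`v > 0` means visible).
#'
#' @param path JSON file.
#' @return list with `observations` and `boxes` data frames (see package
#'   conventions), plus `images` (frame_id, width, height).
#' @export
read_coco_keypoints <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path, class = "io_error")
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  kp_names <- j$categories[[1]]$keypoints
  if (!identical(kp_names, as.list(FISH_KEYPOINTS)) &&
      !identical(unlist(kp_names), FISH_KEYPOINTS))
    stopf("category keypoints are not the 4-point fish schema", class = "schema_error")
  imgs <- do.call(rbind, lapply(j$images, function(im)
    data.frame(frame_id = as.character(im$id), width = im$width,
               height = im$height, stringsAsFactors = FALSE)))
  if (is.null(imgs)) imgs <- data.frame(frame_id = character(), width = numeric(),
                                        height = numeric())
  obs <- empty_observations(); boxes <- empty_boxes()
  if (length(j$annotations)) {
    obs_l <- vector("list", length(j$annotations))
    box_l <- vector("list", length(j$annotations))
    for (i in seq_along(j$annotations)) {
      a <- j$annotations[[i]]
      k <- matrix(unlist(a$keypoints), ncol = 3, byrow = TRUE)
      score <- if (is.null(a$score)) 1 else a$score
      depth <- if (is.null(a$depth_m)) rep(NA_real_, 4) else unlist(a$depth_m)
      obs_l[[i]] <- data.frame(frame_id = as.character(a$image_id),
                               fish_id = as.character(a$id),
                               keypoint = FISH_KEYPOINTS,
                               u = k[, 1], v = k[, 2], visible = k[, 3] > 0,
                               depth_m = depth, score = score,
                               stringsAsFactors = FALSE)
      b <- unlist(a$bbox)  # COCO: x, y, w, h
      box_l[[i]] <- data.frame(frame_id = as.character(a$image_id),
                               fish_id = as.character(a$id),
                               x_min = b[1], y_min = b[2],
                               x_max = b[1] + b[3], y_max = b[2] + b[4],
                               score = score, stringsAsFactors = FALSE)
    }
    obs <- do.call(rbind, obs_l); boxes <- do.call(rbind, box_l)
  }
  list(observations = check_schema(obs), boxes = boxes, images = imgs)
}

#' Write COCO-keypoint annotations
#'
#' @param observations,boxes data frames in the package layout.
#' @param path output JSON file.
#' @param width,height image extent in pixels, recorded per frame.
#' @return `path`, invisibly.
#' @export
write_coco_keypoints <- function(observations, boxes, path, width, height) {
  check_schema(observations)
  frames <- unique(c(observations$frame_id, boxes$frame_id))
  images <- lapply(frames, function(f)
    list(id = f, width = width, height = height))
  anns <- list()
  if (nrow(observations)) {
    split_obs <- split(observations,
                       paste(observations$frame_id, observations$fish_id, sep = "\r"))
    anns <- lapply(split_obs, function(d) {
      d <- d[match(FISH_KEYPOINTS, d$keypoint), ]
      b <- boxes[boxes$frame_id == d$frame_id[1] & boxes$fish_id == d$fish_id[1], ]
      bbox <- if (nrow(b)) c(b$x_min, b$y_min, b$x_max - b$x_min, b$y_max - b$y_min)
              else {
                vis <- d$visible
                c(min(d$u[vis]), min(d$v[vis]),
                  diff(range(d$u[vis])), diff(range(d$v[vis])))
              }
      out <- list(id = d$fish_id[1], image_id = d$frame_id[1], category_id = 1,
                  keypoints = as.numeric(t(cbind(d$u, d$v, as.integer(d$visible) * 2))),
                  num_keypoints = sum(d$visible),
                  bbox = as.numeric(bbox), area = as.numeric(bbox[3] * bbox[4]),
                  score = d$score[1])
      if (any(is.finite(d$depth_m))) out$depth_m <- d$depth_m
      out
    })
    names(anns) <- NULL
  }
  j <- list(images = images, annotations = anns,
            categories = list(list(id = 1, name = "fish",
                                   keypoints = as.list(FISH_KEYPOINTS),
                                   skeleton = list(c(1, 2), c(3, 4)))))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read YOLO-pose labels for one frame
#'
#' Lines of `cls cx cy w h x1 y1 v1 ... x4 y4 v4`, all coordinates
#' normalized to the image extent.
#'
#' @param path label text file.
#' @param width,height image extent in pixels used to de-normalize.
#' @param frame_id identifier to stamp on the rows.
#' @return list with `observations` and `boxes` data frames.
#' @export
read_yolo_pose <- function(path, width, height, frame_id = basename(path)) {
  if (!file.exists(path)) stopf("file not found: %s", path, class = "io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  obs <- empty_observations(); boxes <- empty_boxes()
  if (length(lines)) {
    obs_l <- box_l <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      f <- scan(text = lines[i], quiet = TRUE)
      if (length(f) != 5 + 3 * 4)
        stopf("malformed YOLO-pose line (expected 17 fields, got %d)", length(f),
              class = "schema_error")
      k <- matrix(f[6:17], ncol = 3, byrow = TRUE)
      fid <- sprintf("%s_%d", frame_id, i)
      obs_l[[i]] <- data.frame(frame_id = frame_id, fish_id = fid,
                               keypoint = FISH_KEYPOINTS,
                               u = k[, 1] * width, v = k[, 2] * height,
                               visible = k[, 3] > 0, depth_m = NA_real_,
                               score = 1, stringsAsFactors = FALSE)
      cx <- f[2] * width; cy <- f[3] * height
      bw <- f[4] * width; bh <- f[5] * height
      box_l[[i]] <- data.frame(frame_id = frame_id, fish_id = fid,
                               x_min = cx - bw / 2, y_min = cy - bh / 2,
                               x_max = cx + bw / 2, y_max = cy + bh / 2,
                               score = 1, stringsAsFactors = FALSE)
    }
    obs <- do.call(rbind, obs_l); boxes <- do.call(rbind, box_l)
  }
  list(observations = obs, boxes = boxes)
}

#' Write YOLO-pose labels for one frame
#'
#' @param observations,boxes data frames restricted to one frame.
#' @param path output text file.
#' @param width,height image extent in pixels used to normalize.
#' @return `path`, invisibly.
#' @export
write_yolo_pose <- function(observations, boxes, path, width, height) {
  check_schema(observations)
  ids <- unique(observations$fish_id)
  lines <- vapply(ids, function(id) {
    d <- observations[observations$fish_id == id, ]
    d <- d[match(FISH_KEYPOINTS, d$keypoint), ]
    b <- boxes[boxes$fish_id == id, ]
    if (!nrow(b)) stopf("no box for fish %s", id, class = "schema_error")
    kp <- as.numeric(t(cbind(d$u / width, d$v / height, as.integer(d$visible) * 2)))
    paste(c(0,
            (b$x_min + b$x_max) / 2 / width, (b$y_min + b$y_max) / 2 / height,
            (b$x_max - b$x_min) / width, (b$y_max - b$y_min) / height,
            kp), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
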