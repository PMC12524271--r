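# Detection, keypoint and regression evaluation metrics.

#' Intersection over union of two boxes
#'
#' @param a,b boxes as `c(x_min, y_min, x_max, y_max)` in pixels.
#' @return IoU in [0, 1]; 0 for disjoint boxes.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
#' @export
iou <- function(a, b) {
  check_box <- function(x) {
    if (length(x) != 4 || x[1] >= x[3] || x[2] >= x[4])
      stopf("degenerate box", class = "domain_error")
  }
  check_box(a); check_box(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

#' Object keypoint similarity
#'
#' Gaussian similarity between predicted and true keypoints, averaged over
#' the visible ground-truth points:
#' `sum_i exp(-d_i^2 / (2 * s^2 * sigma_i^2)) * [v_i > 0] / sum_i [v_i > 0]`
#' with the scale taken as `s^2 = area` of the ground-truth box (the COCO
#' convention; with `s = sqrt(area)` the two published readings of the
#' denominator differ only by a reparametrization of sigma). Invisible
#' ground-truth keypoints never contribute, however badly they are
#' predicted.
#'
#' @param pred n x 2 matrix of predicted keypoint (u, v), pixels.
#' @param gt n x 2 matrix of true keypoint positions.
#' @param visible logical vector, length n; at least one TRUE.
#' @param area ground-truth box area in pixels^2 (> 0).
#' @param sigmas per-keypoint tolerance sigma_i; default 0.05 for each of
#'   the four fish keypoints (fish-specific values are unpublished, so the
#'   default must be explicit for reproducibility).
#' @return OKS in [0, 1].
#' @export
oks <- function(pred, gt, visible, area, sigmas = rep(0.05, nrow(gt))) {
  pred <- as.matrix(pred); gt <- as.matrix(gt)
  if (!any(visible))
    stopf("OKS undefined: no visible ground-truth keypoints", class = "undefined_oks_error")
  if (!is.finite(area) || area <= 0) stopf("area must be positive", class = "domain_error")
  d2 <- rowSums((pred - gt)^2)
  e <- exp(-d2 / (2 * area * sigmas^2))
  sum(e[visible]) / sum(visible)
}

#' Greedy score-ordered matching of detections to ground truth
#'
#' COCO-style matching within one image and class: detections are visited
#' in descending score; each claims the unmatched ground truth of highest
#' similarity, provided that similarity reaches the threshold (one-to-one).
#' Unmatched detections are false positives; unmatched ground truths are
#' false negatives.
#'
#' @param detections data.frame with `score` plus either boxes
#'   (`x_min..y_max`) for `similarity = "iou"` or a `keypoints` list-column
#'   of n x 2 matrices for `similarity = "oks"`.
#' @param truths data.frame of ground truths: boxes, and for OKS also
#'   `keypoints` (n x 2 matrices), `visible` (logical vectors) and `area`.
#' @param similarity "iou" or "oks".
#' @param threshold matching cutoff.
#' @param sigmas forwarded to [oks()].
#' @return list with `labels` (data.frame: score, tp ordered by descending
#'   score) and `fn` (count of unmatched ground truths).
#' @export
match_detections <- function(detections, truths, similarity = c("iou", "oks"),
                             threshold = 0.5, sigmas = rep(0.05, 4)) {
  similarity <- match.arg(similarity)
  nd <- if (is.null(detections)) 0L else nrow(detections)
  ng <- if (is.null(truths)) 0L else nrow(truths)
  if (nd == 0L)
    return(list(labels = data.frame(score = numeric(), tp = logical()), fn = ng))
  ord <- order(-detections$score)
  matched_gt <- rep(FALSE, ng)
  tp <- logical(nd)
  sim_fun <- function(di, gi) {
    if (similarity == "iou") {
      iou(as.numeric(detections[di, c("x_min", "y_min", "x_max", "y_max")]),
          as.numeric(truths[gi, c("x_min", "y_min", "x_max", "y_max")]))
    } else {
      vis <- truths$visible[[gi]]
      if (!any(vis)) return(-Inf)
      oks(detections$keypoints[[di]], truths$keypoints[[gi]],
          vis, truths$area[[gi]], sigmas = sigmas)
    }
  }
  for (d in ord) {
    if (ng == 0L) break
    sims <- vapply(seq_len(ng), function(g)
      if (matched_gt[g]) -Inf else sim_fun(d, g), numeric(1))
    g_best <- which.max(sims)
    if (length(g_best) && sims[g_best] >= threshold) {
      matched_gt[g_best] <- TRUE
      tp[d] <- TRUE
    }
  }
  list(labels = data.frame(score = detections$score[ord], tp = tp[ord]),
       fn = sum(!matched_gt))
}

#' Precision-recall curve from matched detections
#'
#' Pools labeled detections across images, sorts by descending score and
#' accumulates `precision = TP / (TP + FP)` and `recall = TP / n_gt`.
#'
#' @param labels data.frame with `score` and logical `tp` (rbind the
#'   `labels` of per-image [match_detections()] results).
#' @param n_gt total number of ground-truth objects (> 0).
#' @return object of class `pr_curve`: data.frame with `recall`,
#'   `precision` in global descending-score order.
#' @export
pr_curve <- function(labels, n_gt) {
  if (n_gt <= 0) stopf("recall undefined with zero ground truths",
                       class = "undefined_recall_error")
  labels <- labels[order(-labels$score), , drop = FALSE]
  tp_cum <- cumsum(labels$tp)
  k <- seq_len(nrow(labels))
  structure(data.frame(recall = tp_cum / n_gt, precision = tp_cum / k),
            class = c("pr_curve", "data.frame"), n_gt = n_gt)
}

#' Interpolated average precision
#'
#' Area under the precision envelope `P_interp(r) = max_{r' >= r} P(r')`.
#' `"all_point"` sums envelope precision times recall increments at every
#' detection rank; `"coco101"` samples the envelope at the 101 recalls
#' 0, 0.01, ..., 1 and averages, for parity with COCO tooling.
#'
#' @param curve a [pr_curve()].
#' @param interpolation "all_point" (default) or "coco101".
#' @return AP in [0, 1]; an empty curve gives 0 with a warning.
#' @export
average_precision <- function(curve, interpolation = c("all_point", "coco101")) {
  interpolation <- match.arg(interpolation)
  if (!nrow(curve)) {
    warnf("empty precision-recall curve; AP = 0")
    return(0)
  }
  r <- curve$recall; p <- curve$precision
  # precision envelope from the right
  penv <- rev(cummax(rev(p)))
  if (interpolation == "all_point") {
    dr <- diff(c(0, r))
    sum(penv * dr)
  } else {
    grid <- seq(0, 1, by = 0.01)
    vals <- vapply(grid, function(g) {
      i <- which(r >= g - 1e-12)
      if (!length(i)) 0 else penv[i[1]]
    }, numeric(1))
    mean(vals)
  }
}

#' Mean average precision
#'
#' Arithmetic mean of per-class APs; with one class mAP equals AP.
#'
#' @param aps numeric vector of per-class AP values (one threshold), or a
#'   matrix with classes in rows and thresholds in columns.
#' @return mean AP.
#' @export
mean_ap <- function(aps) {
  if (is.matrix(aps)) mean(colMeans(aps)) else mean(aps)
}

#' Evaluate a detection set at COCO threshold ranges
#'
#' Convenience wrapper computing mAP50 and mAP50-95 (thresholds
#' 0.50, 0.55, ..., 0.95) for boxes (IoU) or keypoints (OKS) over a list of
#' per-image detection/truth pairs, single class.
#'
#' @param scenes list of lists with elements `detections` and `truths` as in
#'   [match_detections()].
#' @param similarity "iou" or "oks".
#' @param sigmas forwarded to [oks()].
#' @param interpolation forwarded to [average_precision()].
#' @return list with `map50`, `map50_95`, and `ap_by_threshold`.
#' @export
evaluate_detections <- function(scenes, similarity = c("iou", "oks"),
                                sigmas = rep(0.05, 4),
                                interpolation = "all_point") {
  similarity <- match.arg(similarity)
  thresholds <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(thresholds, function(th) {
    labs <- list(); n_gt <- 0L
    for (sc in scenes) {
      m <- match_detections(sc$detections, sc$truths, similarity = similarity,
                            threshold = th, sigmas = sigmas)
      labs[[length(labs) + 1]] <- m$labels
      n_gt <- n_gt + (if (is.null(sc$truths)) 0L else nrow(sc$truths))
    }
    labels <- do.call(rbind, labs)
    if (is.null(labels) || !nrow(labels)) return(0)
    if (n_gt == 0L) return(0)
    average_precision(pr_curve(labels, n_gt), interpolation = interpolation)
  }, numeric(1))
  list(map50 = aps[1], map50_95 = mean(aps),
       ap_by_threshold = stats::setNames(aps, sprintf("%.2f", thresholds)))
}

#' Regression error metrics
#'
#' MAE, MSE, RMSE and R-squared between true and predicted values. The
#' default R2 is the coefficient of determination `1 - SS_res / SS_tot`;
#' `r2_mode = "pearson"` gives the squared Pearson correlation instead
#' (undefined for constant inputs).
#'
#' @param x true values.
#' @param y predicted values (same length).
#' @param r2_mode "determination" (default) or "pearson".
#' @return list with `MAE`, `MSE`, `RMSE`, `R2`.
#' @examples
#' regression_metrics(c(1, 2), c(2, 4))  # MAE 1.5, MSE 2.5
#' @export
regression_metrics <- function(x, y, r2_mode = c("determination", "pearson")) {
  r2_mode <- match.arg(r2_mode)
  if (length(x) != length(y) || !length(x))
    stopf("x and y must have equal, nonzero length", class = "domain_error")
  err <- x - y
  mse <- mean(err^2)
  r2 <- if (r2_mode == "determination") {
    ss_tot <- sum((x - mean(x))^2)
    if (ss_tot == 0) {
      if (mse == 0) 1 else -Inf
    } else 1 - sum(err^2) / ss_tot
  } else {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stopf("Pearson R2 undefined for constant input", class = "undefined_r2_error")
    stats::cor(x, y)^2
  }
  list(MAE = mean(abs(err)), MSE = mse, RMSE = sqrt(mse), R2 = r2)
}
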