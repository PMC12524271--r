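# Independent COCO-style keypoint-evaluation reference, written as plain
# loops with its own greedy matcher and a brute-force average-precision
# integration over distinct recall levels. Deliberately shares no code with
# the package implementation; used as the oracle for OKS/AP equivalence.

ref_oks <- function(pred, gt, vis, area, sigmas) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(gt))) {
    if (vis[i]) {
      d2 <- (pred[i, 1] - gt[i, 1])^2 + (pred[i, 2] - gt[i, 2])^2
      num <- num + exp(-d2 / (2 * area * sigmas[i]^2))
      den <- den + 1
    }
  }
  num / den
}

ref_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / ((a[3]-a[1]) * (a[4]-a[2]) + (b[3]-b[1]) * (b[4]-b[2]) - inter)
}

# greedy score-descending one-to-one matcher; returns scored TP/FP labels
# and the false-negative count
ref_match <- function(scene, similarity, threshold, sigmas) {
  det <- scene$detections; gt <- scene$truths
  taken <- rep(FALSE, nrow(gt))
  lab <- data.frame(score = numeric(0), tp = logical(0))
  for (d in order(det$score, decreasing = TRUE)) {
    best_s <- -1; best_g <- 0
    for (g in seq_len(nrow(gt))) {
      if (taken[g]) next
      s <- if (similarity == "iou") {
        ref_iou(as.numeric(det[d, c("x_min","y_min","x_max","y_max")]),
                as.numeric(gt[g, c("x_min","y_min","x_max","y_max")]))
      } else {
        ref_oks(det$keypoints[[d]], gt$keypoints[[g]], gt$visible[[g]],
                gt$area[[g]], sigmas)
      }
      if (s > best_s) { best_s <- s; best_g <- g }
    }
    hit <- best_g > 0 && best_s >= threshold
    if (hit) taken[best_g] <- TRUE
    lab <- rbind(lab, data.frame(score = det$score[d], tp = hit))
  }
  list(labels = lab, fn = sum(!taken))
}

# all-point interpolated AP by explicit envelope integration over every
# distinct recall level
ref_ap <- function(scores, tp, n_gt) {
  ord <- order(scores, decreasing = TRUE)
  tp <- tp[ord]
  n <- length(tp)
  if (n == 0 || n_gt == 0) return(0)
  tpc <- cumsum(tp)
  prec <- tpc / seq_len(n)
  rec <- tpc / n_gt
  ap <- 0; prev_r <- 0
  for (k in seq_len(n)) {
    r_prev <- if (k == 1) 0 else rec[k - 1]
    if (rec[k] > r_prev) {
      p_interp <- max(prec[k:n])
      ap <- ap + p_interp * (rec[k] - prev_r)
      prev_r <- rec[k]
    }
  }
  ap
}

ref_evaluate <- function(scenes, similarity, threshold, sigmas = rep(0.05, 4)) {
  scores <- numeric(0); tp <- logical(0); n_gt <- 0
  for (sc in scenes) {
    m <- ref_match(sc, similarity, threshold, sigmas)
    scores <- c(scores, m$labels$score)
    tp <- c(tp, m$labels$tp)
    n_gt <- n_gt + nrow(sc$truths)
  }
  ref_ap(scores, tp, n_gt)
}
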