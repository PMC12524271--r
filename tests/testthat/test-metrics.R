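test_that("IoU matches hand-computed overlaps", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_equal(iou(c(1, 0, 3, 2), c(0, 0, 2, 2)), 1 / 3)  # symmetric
  expect_error(iou(c(0, 0, 0, 2), c(0, 0, 1, 1)), class = "domain_error")
})

test_that("OKS follows the area-scaled Gaussian with a visibility mask", {
  gt <- cbind(c(10, 50, 30, 30), c(10, 10, 0, 20))
  vis <- rep(TRUE, 4)
  expect_equal(oks(gt, gt, vis, area = 1200), 1)
  # one visible point displaced so d^2 = 2 * area * sigma^2 gives exp(-1)
  area <- 900; sigma <- 0.1
  d <- sqrt(2 * area * sigma^2)
  pred1 <- cbind(10 + d, 10)
  expect_equal(oks(pred1, cbind(10, 10), TRUE, area, sigmas = sigma), exp(-1),
               tolerance = 1e-12)
  # arbitrarily misplaced invisible points do not change the score
  pred <- gt; pred[2, ] <- c(1e6, 1e6)
  vis2 <- c(TRUE, FALSE, TRUE, TRUE)
  expect_equal(oks(pred, gt, vis2, 1200), 1)
  expect_error(oks(gt, gt, rep(FALSE, 4), 1200), class = "undefined_oks_error")
})

test_that("greedy matching is one-to-one in score order", {
  gt_box <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  # two detections over one ground truth: only the higher-scored one matches
  det <- data.frame(x_min = c(0, 1), y_min = c(0, 0), x_max = c(10, 10),
                    y_max = c(10, 10), score = c(0.9, 0.95))
  m <- match_detections(det, gt_box, similarity = "iou", threshold = 0.5)
  expect_equal(m$labels$tp, c(TRUE, FALSE))   # ordered by descending score
  expect_equal(m$fn, 0)
  # perfect one-to-one detections: all TP
  gts <- data.frame(x_min = c(0, 20), y_min = 0, x_max = c(10, 30), y_max = 10)
  dets <- transform(gts, score = c(0.8, 0.7))
  m2 <- match_detections(dets, gts, similarity = "iou", threshold = 0.5)
  expect_true(all(m2$labels$tp))
  expect_equal(m2$fn, 0)
  # empty inputs are valid
  m3 <- match_detections(dets[0, ], gts, similarity = "iou")
  expect_equal(nrow(m3$labels), 0L)
  expect_equal(m3$fn, 2)
})

test_that("greedy matching agrees with the loop-coded reference on small scenes", {
  set.seed(77)
  for (i in 1:20) {
    sc <- random_metric_scene(sample(1:5, 1), sample(0:3, 1))
    for (sim in c("iou", "oks")) {
      m <- match_detections(sc$detections, sc$truths, similarity = sim,
                            threshold = 0.5)
      r <- ref_match(sc, sim, 0.5, rep(0.05, 4))
      expect_equal(m$labels$tp, r$labels$tp)
      expect_equal(m$fn, r$fn)
    }
  }
})

test_that("precision-recall bookkeeping matches hand counts", {
  labels <- data.frame(score = c(0.9, 0.8, 0.7), tp = c(TRUE, FALSE, TRUE))
  c1 <- pr_curve(labels, n_gt = 2)
  expect_equal(c1$precision, c(1, 1 / 2, 2 / 3))
  expect_equal(c1$recall, c(1 / 2, 1 / 2, 1))
  expect_true(all(diff(c1$recall) >= 0))
  # all-point AP: 0.5 * 1 + 0.5 * (2/3)
  expect_equal(average_precision(c1), 5 / 6)
  # perfect ranking
  perfect <- pr_curve(data.frame(score = c(0.9, 0.8), tp = c(TRUE, TRUE)), 2)
  expect_equal(average_precision(perfect), 1)
  # all false positives
  allfp <- pr_curve(data.frame(score = c(0.9, 0.8), tp = c(FALSE, FALSE)), 2)
  expect_equal(allfp$precision, c(0, 0))
  expect_equal(average_precision(allfp), 0)
  expect_error(pr_curve(labels, 0), class = "undefined_recall_error")
  expect_warning(ap0 <- average_precision(pr_curve(labels[0, ], 2)))
  expect_equal(ap0, 0)
})

test_that("all-point AP equals brute-force envelope integration on random rankings", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(1:10, 1)
    tp <- runif(n) > 0.5
    n_gt <- max(sum(tp), 1) + sample(0:3, 1)
    scores <- runif(n)
    labels <- data.frame(score = scores, tp = tp)
    expect_equal(average_precision(pr_curve(labels, n_gt)),
                 ref_ap(scores, tp, n_gt), tolerance = 1e-12)
  }
})

test_that("mAP averages classes and thresholds consistently", {
  expect_equal(mean_ap(c(0.8, 0.6)), 0.7)
  expect_equal(mean_ap(0.83), 0.83)  # single class: mAP == AP
  set.seed(55)
  scenes <- lapply(1:4, function(i) random_metric_scene(4, 2))
  ev <- evaluate_detections(scenes, similarity = "iou")
  expect_lte(ev$map50_95, ev$map50 + 1e-12)
  # AP is non-increasing in the matching threshold for a fixed detection set
  expect_true(all(diff(ev$ap_by_threshold) <= 1e-12))
})

test_that("regression metrics match hand arithmetic and satisfy their identities", {
  m <- regression_metrics(c(1, 2), c(2, 4))
  expect_equal(m$MAE, 1.5)
  expect_equal(m$MSE, 2.5)
  expect_equal(m$RMSE, sqrt(2.5))
  perfect <- regression_metrics(c(3, 3), c(3, 3))
  expect_equal(perfect$MAE, 0)
  expect_equal(perfect$R2, 1)
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(30); y <- x + rnorm(30, 0, 0.5)
    mm <- regression_metrics(x, y)
    expect_equal(mm$RMSE^2, mm$MSE, tolerance = 1e-12)
    expect_lte(mm$MAE, mm$RMSE + 1e-12)   # Jensen
  }
  expect_error(regression_metrics(1:3, 1:2), class = "domain_error")
  expect_error(regression_metrics(rep(1, 5), 1:5, r2_mode = "pearson"),
               class = "undefined_r2_error")
  # the two R2 conventions coincide for an OLS fit, not in general
  x <- rnorm(50); y <- 2 + 0.5 * x + rnorm(50, 0, 0.1)
  fit <- lm(y ~ x)
  expect_equal(regression_metrics(y, fitted(fit))$R2,
               regression_metrics(y, fitted(fit), r2_mode = "pearson")$R2,
               tolerance = 1e-9)
})
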