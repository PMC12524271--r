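zero_params <- function(m) {
  m$params <- lapply(m$params, function(p) { p[] <- 0; p })
  m$modules <- lapply(m$modules, zero_params)
  m
}

test_that("single-layer parameter counts match the closed forms", {
  expect_equal(count_parameters(nn_conv2d(4, 8, kernel = 3)), 4 * 8 * 9 + 8)
  expect_equal(count_parameters(nn_conv2d(8, 8, kernel = 3, groups = 8)),
               8 * 9 + 8)
  expect_equal(count_parameters(nn_conv2d(16, 32, kernel = 1, bias = FALSE)),
               16 * 32)
  expect_equal(count_parameters(nn_batchnorm2d(12)), 24)
  # double depthwise layers are strictly cheaper than standard convs of the
  # same channel width
  c <- 32
  dw2 <- count_parameters(nn_conv2d(c, c, 3, groups = c)) * 2
  std2 <- count_parameters(nn_conv2d(c, c, 3)) * 2
  expect_lt(dw2, std2)
})

test_that("hceblock preserves shape and isolates its residual branch", {
  set.seed(1)
  b <- hceblock(8, 12)
  x <- array(rnorm(2 * 8 * 9 * 11), c(2, 8, 9, 11))
  y <- forward(b, x)
  expect_equal(dim(y), c(2, 12, 9, 11))
  expect_gt(sd(y), 0)  # no dead path
  # zeroing the main branch leaves exactly the residual convolution
  b0 <- b
  for (nm in c("dw", "bn", "pw")) b0$modules[[nm]] <- zero_params(b0$modules[[nm]])
  expect_equal(forward(b0, x), forward(b$modules$res, x), tolerance = 1e-12)
  expect_error(forward(b, array(0, c(1, 5, 4, 4))), class = "config_error")
})

test_that("gdcblock gates in (0,1) and reduces to the identity under zeroed weights", {
  set.seed(2)
  g <- gdcblock(8, 8)
  x <- array(rnorm(1 * 8 * 12 * 12), c(1, 8, 12, 12))
  y <- forward(g, x)
  expect_equal(dim(y), dim(x))
  gate <- gdc_gate(g, x)
  expect_true(all(gate > 0 & gate < 1))
  # all non-residual weights and biases zeroed: pure residual pass-through
  g0 <- zero_params(g)
  expect_equal(forward(g0, x), x, tolerance = 1e-12)
  expect_error(gdcblock(8, 16), class = "config_error")  # strict residual
  g2 <- gdcblock(8, 16, strict = FALSE)
  expect_equal(dim(forward(g2, x)), c(1, 16, 12, 12))
})

test_that("hgcblock splits channels as configured and preserves shape", {
  set.seed(3)
  h <- hgcblock(64, 64, hidden_ratio = 0.5)
  expect_equal(h$meta$c_enh, 32)
  expect_equal(h$modules$enh$meta$in_channels, 32)
  x <- array(rnorm(1 * 64 * 8 * 8), c(1, 64, 8, 8))
  expect_equal(dim(forward(h, x)), dim(x))
  expect_error(hgcblock(8, 8, hidden_ratio = 0), class = "config_error")
  expect_error(hgcblock(8, 2, hidden_ratio = 0.1), class = "config_error")
})

test_that("hgcblock routes gradient through both split halves", {
  set.seed(4)
  h <- hgcblock(4, 4, hidden_ratio = 0.5)
  x <- array(rnorm(1 * 4 * 5 * 5), c(1, 4, 5, 5))
  base <- sum(forward(h, x))
  eps <- 1e-5
  # finite-difference sensitivity w.r.t. an input unit in each half of the
  # post-split channel range must be nonzero
  sens <- vapply(1:4, function(c) {
    xp <- x; xp[1, c, 3, 3] <- xp[1, c, 3, 3] + eps
    (sum(forward(h, xp)) - base) / eps
  }, numeric(1))
  expect_true(all(abs(sens) > 1e-8))
})

test_that("the pyramid neck is top-down only with uniform output width", {
  set.seed(5)
  neck <- fpn_neck(c(8, 16, 32), 16)
  feats <- list(array(rnorm(8 * 16 * 16), c(1, 8, 16, 16)),
                array(rnorm(16 * 8 * 8), c(1, 16, 8, 8)),
                array(rnorm(32 * 4 * 4), c(1, 32, 4, 4)))
  out <- forward(neck, feats)
  expect_equal(lapply(out, dim),
               list(c(1, 16, 16, 16), c(1, 16, 8, 8), c(1, 16, 4, 4)))
  # perturbing P5 reaches the P3 output...
  f2 <- feats; f2[[3]][1, 1, 2, 2] <- f2[[3]][1, 1, 2, 2] + 1
  out2 <- forward(neck, f2)
  expect_gt(max(abs(out2[[1]] - out[[1]])), 0)
  # ...but perturbing P3 never reaches P5
  f3 <- feats; f3[[1]][1, 1, 2, 2] <- f3[[1]][1, 1, 2, 2] + 1
  out3 <- forward(neck, f3)
  expect_equal(out3[[3]], out[[3]])
  expect_error(forward(neck, list(feats[[1]], feats[[2]], feats[[2]])),
               class = "shape_error")
})

test_that("the pose head emits the documented per-location output width", {
  set.seed(6)
  head <- pose_head(16, n_classes = 1, reg_bins = 16, n_keypoints = 4)
  x <- array(rnorm(16 * 6 * 6), c(1, 16, 6, 6))
  out <- forward(head, list(x))[[1]]
  expect_equal(dim(out$box)[2], 64)
  expect_equal(dim(out$cls)[2], 1)
  expect_equal(dim(out$keypoints)[2], 12)  # 4 keypoints x (x, y, confidence)
  expect_equal(head_output_width(head), 1 + 64 + 12)
})

test_that("forward contracts hold identically for single and batched input", {
  set.seed(7)
  g <- gdcblock(6, 6)
  x1 <- array(rnorm(6 * 7 * 7), c(1, 6, 7, 7))
  x2 <- array(rnorm(6 * 7 * 7), c(1, 6, 7, 7))
  xb <- array(0, c(2, 6, 7, 7))
  xb[1, , , ] <- x1; xb[2, , , ] <- x2
  yb <- forward(g, xb)
  expect_equal(yb[1, , , , drop = FALSE], forward(g, x1), tolerance = 1e-12)
  expect_equal(yb[2, , , , drop = FALSE], forward(g, x2), tolerance = 1e-12)
})

test_that("the assembled network validates 640x640 shape flow and is seed-reproducible", {
  net <- keypoint_net(widths = c(8, 16, 24, 32, 48), neck_width = 16, seed = 3)
  net2 <- keypoint_net(widths = c(8, 16, 24, 32, 48), neck_width = 16, seed = 3)
  expect_identical(net, net2)
  flow <- shape_flow(net, 640, 640)
  expect_equal(flow$height[flow$stage == "stage2 /8 (P3)"], 80)
  expect_equal(flow$height[flow$stage == "stage4 /32 (P5)"], 20)
  expect_equal(flow$height[grepl("head", flow$stage)], c(80, 40, 20))
  expect_true(all(flow$channels[grepl("neck", flow$stage)] == 16))
  expect_error(shape_flow(net, 100, 100), class = "shape_error")
  # the numeric forward agrees with the symbolic flow on a small input
  set.seed(8)
  out <- forward(net, array(rnorm(3 * 64 * 64), c(1, 3, 64, 64)))
  expect_equal(dim(out[[1]]$keypoints), c(1, 12, 8, 8))
  expect_equal(dim(out[[3]]$box), c(1, 64, 2, 2))
  counts <- count_parameters(net)
  expect_equal(counts, sum(vapply(net$modules, count_parameters, numeric(1))))
})
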