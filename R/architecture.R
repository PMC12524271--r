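# Structural building blocks of the fish keypoint-detection network: the
# hybrid convolutional enhancement block (dual-branch residual), the gated
# depthwise convolutional block (sigmoid-gated three-way feature fusion),
# their CSP-style composition, a top-down feature pyramid neck, and a pose
# head with double depthwise-convolution branches. "Deep convolution" is
# realized as depthwise convolution throughout. The contracts implemented
# and tested here are architectural (shape preservation, gate range,
# residual identities, exact parameter counts); training is a non-goal.

#' Hybrid convolutional enhancement block
#'
#' Dual-branch residual unit: the main branch is
#' `activation(conv1x1(batchnorm(depthwise_kxk(x))))` (deep features), the
#' residual branch a standard 1x1 convolution (shallow features); the
#' output is their elementwise sum. Stride 1, spatial dims preserved.
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel depthwise kernel size (default 3).
#' @param activation activation name (default "silu").
#' @return an `sf_hceblock` module.
#' @export
hceblock <- function(in_channels, out_channels, kernel = 3, activation = "silu") {
  sf_module("sf_hceblock",
    modules = list(
      dw = nn_conv2d(in_channels, in_channels, kernel, groups = in_channels),
      bn = nn_batchnorm2d(in_channels),
      pw = nn_conv2d(in_channels, out_channels, 1),
      res = nn_conv2d(in_channels, out_channels, 1)),
    meta = list(in_channels = in_channels, out_channels = out_channels,
                stride = 1, activation = activation))
}

#' @export
forward.sf_hceblock <- function(m, x, ...) {
  check_channels(x, m$meta$in_channels, "hceblock")
  main <- apply_activation(
    forward(m$modules$pw, forward(m$modules$bn, forward(m$modules$dw, x))),
    m$meta$activation)
  main + forward(m$modules$res, x)
}

#' Gated depthwise convolutional block
#'
#' Stem `conv1x1(batchnorm(depthwise(x)))` producing `3 * hidden` channels
#' split into equal thirds: a gate branch (sigmoid, elementwise in (0, 1)),
#' a spatial branch (further depthwise convolution) and an identity branch.
#' The gate weights both content halves, the weighted pair is concatenated,
#' projected to `out_channels` and added to the input residually.
#'
#' @param in_channels,out_channels channel counts; the residual add
#'   requires `in_channels == out_channels` when `strict = TRUE` (default),
#'   otherwise a 1x1 projection is inserted on the skip path.
#' @param hidden per-branch hidden width (default `out_channels / 2`,
#'   minimum 1).
#' @param kernel depthwise kernel size.
#' @param strict error on channel mismatch instead of projecting.
#' @return an `sf_gdcblock` module.
#' @export
gdcblock <- function(in_channels, out_channels, hidden = max(1L, out_channels %/% 2L),
                     kernel = 3, strict = TRUE) {
  if (in_channels != out_channels && strict)
    stopf("gdcblock residual requires in_channels == out_channels (strict)",
          class = "config_error")
  mods <- list(
    dw = nn_conv2d(in_channels, in_channels, kernel, groups = in_channels),
    bn = nn_batchnorm2d(in_channels),
    stem = nn_conv2d(in_channels, 3L * hidden, 1),
    spatial_dw = nn_conv2d(hidden, hidden, kernel, groups = hidden),
    proj = nn_conv2d(2L * hidden, out_channels, 1))
  if (in_channels != out_channels)
    mods$skip <- nn_conv2d(in_channels, out_channels, 1)
  sf_module("sf_gdcblock", modules = mods,
            meta = list(in_channels = in_channels, out_channels = out_channels,
                        hidden = hidden, stride = 1))
}

#' @export
forward.sf_gdcblock <- function(m, x, ...) {
  check_channels(x, m$meta$in_channels, "gdcblock")
  h <- m$meta$hidden
  stem <- forward(m$modules$stem,
                  forward(m$modules$bn, forward(m$modules$dw, x)))
  gate <- sigmoid(stem[, seq_len(h), , , drop = FALSE])
  spatial <- forward(m$modules$spatial_dw, stem[, h + seq_len(h), , , drop = FALSE])
  ident <- stem[, 2L * h + seq_len(h), , , drop = FALSE]
  fused <- concat_channels(gate * spatial, gate * ident)
  out <- forward(m$modules$proj, fused)
  skip <- if (is.null(m$modules$skip)) x else forward(m$modules$skip, x)
  out + skip
}

#' Gate activations of a gated block
#'
#' Exposes the sigmoid gate values for a given input (diagnostic; they lie
#' strictly inside (0, 1) for finite input).
#'
#' @param m an `sf_gdcblock`.
#' @param x input array.
#' @return array of gate values.
#' @export
gdc_gate <- function(m, x) {
  stopifnot(inherits(m, "sf_gdcblock"))
  stem <- forward(m$modules$stem,
                  forward(m$modules$bn, forward(m$modules$dw, x)))
  sigmoid(stem[, seq_len(m$meta$hidden), , , drop = FALSE])
}

#' Hybrid gated convolutional block
#'
#' CSP-style composition: a 1x1 convolution, a channel split at
#' `hidden_ratio`, [hceblock()] enhancement of one part, concatenation
#' with the untouched part, a merging 1x1 convolution, then a [gdcblock()]
#' for gated reweighting.
#'
#' @param in_channels,out_channels channel counts.
#' @param hidden_ratio split fraction in (0, 1) routed through the
#'   enhancement path.
#' @param kernel depthwise kernel size for the submodules.
#' @return an `sf_hgcblock` module.
#' @export
hgcblock <- function(in_channels, out_channels, hidden_ratio = 0.5, kernel = 3) {
  if (hidden_ratio <= 0 || hidden_ratio >= 1)
    stopf("hidden_ratio must be in (0, 1)", class = "config_error")
  c_enh <- as.integer(round(out_channels * hidden_ratio))
  if (c_enh < 1L || c_enh >= out_channels)
    stopf("channel split produces an empty branch", class = "config_error")
  sf_module("sf_hgcblock",
    modules = list(
      pre = nn_conv_unit(in_channels, out_channels, 1),
      enh = hceblock(c_enh, c_enh, kernel = kernel),
      merge = nn_conv_unit(out_channels, out_channels, 1),
      gdc = gdcblock(out_channels, out_channels, kernel = kernel)),
    meta = list(in_channels = in_channels, out_channels = out_channels,
                c_enh = c_enh, stride = 1))
}

#' @export
forward.sf_hgcblock <- function(m, x, ...) {
  check_channels(x, m$meta$in_channels, "hgcblock")
  y <- forward(m$modules$pre, x)
  c_enh <- m$meta$c_enh
  a <- y[, seq_len(c_enh), , , drop = FALSE]
  b <- y[, c_enh + seq_len(dim(y)[2] - c_enh), , , drop = FALSE]
  merged <- forward(m$modules$merge, concat_channels(forward(m$modules$enh, a), b))
  forward(m$modules$gdc, merged)
}

#' Top-down feature pyramid neck
#'
#' Lateral 1x1 convolutions bring the three backbone levels (strides
#' 8/16/32) to a common width; the top level is upsampled (nearest, 2x)
#' and merged downward by elementwise sum followed by a 3x3 smoothing
#' convolution. Top-down only: no bottom-up augmentation path, so a
#' perturbation at the coarsest level reaches the finest output but never
#' the reverse.
#'
#' @param in_channels integer vector of 3 input widths (P3, P4, P5).
#' @param out_channels common neck width.
#' @return an `sf_fpn` module.
#' @export
fpn_neck <- function(in_channels, out_channels) {
  stopifnot(length(in_channels) == 3)
  sf_module("sf_fpn",
    modules = list(
      lat3 = nn_conv2d(in_channels[1], out_channels, 1),
      lat4 = nn_conv2d(in_channels[2], out_channels, 1),
      lat5 = nn_conv2d(in_channels[3], out_channels, 1),
      smooth3 = nn_conv2d(out_channels, out_channels, 3),
      smooth4 = nn_conv2d(out_channels, out_channels, 3)),
    meta = list(in_channels = in_channels, out_channels = out_channels))
}

#' @export
forward.sf_fpn <- function(m, x, ...) {
  stopifnot(is.list(x), length(x) == 3)
  d3 <- dim(x[[1]]); d4 <- dim(x[[2]]); d5 <- dim(x[[3]])
  if (!all(d3[3:4] == 2L * d4[3:4]) || !all(d4[3:4] == 2L * d5[3:4]))
    stopf("pyramid levels must have 2x spatial ratios", class = "shape_error")
  p5 <- forward(m$modules$lat5, x[[3]])
  p4 <- forward(m$modules$smooth4, forward(m$modules$lat4, x[[2]]) + upsample2x(p5))
  p3 <- forward(m$modules$smooth3, forward(m$modules$lat3, x[[1]]) + upsample2x(p4))
  list(p3, p4, p5)
}

#' Keypoint-detection pose head
#'
#' Per scale, three branches — bounding-box regression, classification and
#' keypoints — each applying two depthwise 3x3 convolution layers before
#' its final 1x1 projection. Per-location output width is
#' `n_classes + 4 * reg_bins + n_keypoints * 3` (x, y, confidence per
#' keypoint; 12 keypoint channels for the 4-point fish schema).
#'
#' @param in_channels feature width at every scale (post-neck).
#' @param n_classes number of object classes (default 1: fish).
#' @param reg_bins distribution bins per box side (default 16).
#' @param n_keypoints keypoints per object (default 4).
#' @return an `sf_pose_head` module.
#' @export
pose_head <- function(in_channels, n_classes = 1, reg_bins = 16, n_keypoints = 4) {
  branch <- function(out) list(
    dw1 = nn_conv2d(in_channels, in_channels, 3, groups = in_channels),
    dw2 = nn_conv2d(in_channels, in_channels, 3, groups = in_channels),
    proj = nn_conv2d(in_channels, out, 1))
  mods <- c(stats::setNames(branch(4 * reg_bins), c("box_dw1", "box_dw2", "box_proj")),
            stats::setNames(branch(n_classes), c("cls_dw1", "cls_dw2", "cls_proj")),
            stats::setNames(branch(3 * n_keypoints), c("kp_dw1", "kp_dw2", "kp_proj")))
  sf_module("sf_pose_head", modules = mods,
            meta = list(in_channels = in_channels, n_classes = n_classes,
                        reg_bins = reg_bins, n_keypoints = n_keypoints))
}

#' @export
forward.sf_pose_head <- function(m, x, ...) {
  if (!is.list(x)) x <- list(x)
  run <- function(feat, pre) {
    b <- forward(m$modules[[paste0(pre, "_proj")]],
                 forward(m$modules[[paste0(pre, "_dw2")]],
                         forward(m$modules[[paste0(pre, "_dw1")]], feat)))
    b
  }
  lapply(x, function(feat) {
    check_channels(feat, m$meta$in_channels, "pose_head")
    list(box = run(feat, "box"), cls = run(feat, "cls"),
         keypoints = run(feat, "kp"))
  })
}

#' Per-location output width of a pose head
#'
#' @param head an `sf_pose_head`.
#' @return `n_classes + 4 * reg_bins + 3 * n_keypoints`.
#' @export
head_output_width <- function(head) {
  with(head$meta, n_classes + 4 * reg_bins + 3 * n_keypoints)
}

# ---- assembled model and shape inference ----------------------------------

#' Assemble the full keypoint-detection network
#'
#' Backbone (stem + four downsampling stages with hybrid gated blocks)
#' feeding a top-down pyramid neck and the pose head at strides 8/16/32.
#' Parameters are drawn from the seed, so a fixed seed reproduces the model
#' bit for bit.
#'
#' @param widths channel widths of the stem and the four stages.
#' @param neck_width common neck/head width.
#' @param n_classes,reg_bins,n_keypoints forwarded to [pose_head()].
#' @param seed init seed.
#' @return an `sf_net` module.
#' @export
keypoint_net <- function(widths = c(16, 32, 64, 128, 256), neck_width = 64,
                         n_classes = 1, reg_bins = 16, n_keypoints = 4,
                         seed = 1) {
  stopifnot(length(widths) == 5)
  with_seed(seed, {
    mods <- list(
      stem = nn_conv_unit(3, widths[1], 3, stride = 2),            # /2
      down1 = nn_conv_unit(widths[1], widths[2], 3, stride = 2),   # /4
      stage1 = hgcblock(widths[2], widths[2]),
      down2 = nn_conv_unit(widths[2], widths[3], 3, stride = 2),   # /8 -> P3
      stage2 = hgcblock(widths[3], widths[3]),
      down3 = nn_conv_unit(widths[3], widths[4], 3, stride = 2),   # /16 -> P4
      stage3 = hgcblock(widths[4], widths[4]),
      down4 = nn_conv_unit(widths[4], widths[5], 3, stride = 2),   # /32 -> P5
      stage4 = hgcblock(widths[5], widths[5]),
      neck = fpn_neck(widths[3:5], neck_width),
      head = pose_head(neck_width, n_classes, reg_bins, n_keypoints))
    sf_module("sf_net", modules = mods,
              meta = list(widths = widths, neck_width = neck_width, seed = seed))
  })
}

#' @export
forward.sf_net <- function(m, x, ...) {
  d <- dim(x)
  if (d[3] %% 32 != 0 || d[4] %% 32 != 0)
    stopf("input spatial dims must be multiples of 32", class = "shape_error")
  mo <- m$modules
  s <- forward(mo$stage1, forward(mo$down1, forward(mo$stem, x)))
  p3 <- forward(mo$stage2, forward(mo$down2, s))
  p4 <- forward(mo$stage3, forward(mo$down3, p3))
  p5 <- forward(mo$stage4, forward(mo$down4, p4))
  forward(mo$head, forward(mo$neck, list(p3, p4, p5)))
}

#' Symbolic shape flow through the assembled network
#'
#' Validates the end-to-end shape contract without running the numeric
#' forward pass: every block is stride-1 shape-preserving, downsampling
#' convs halve the extent, the neck emits `neck_width` channels at strides
#' 8/16/32, and the head emits its per-location width at each grid.
#'
#' @param model an `sf_net`.
#' @param height,width input extent (multiples of 32), default 640 x 640.
#' @return data.frame of stage names and output shapes (channels, h, w).
#' @export
shape_flow <- function(model, height = 640, width = 640) {
  stopifnot(inherits(model, "sf_net"))
  if (height %% 32 != 0 || width %% 32 != 0)
    stopf("input spatial dims must be multiples of 32", class = "shape_error")
  w <- model$meta$widths; nw <- model$meta$neck_width
  head <- model$modules$head
  rows <- list()
  add <- function(stage, ch, h, wd)
    rows[[length(rows) + 1]] <<- data.frame(stage = stage, channels = ch,
                                            height = h, width = wd)
  add("input", 3, height, width)
  add("stem /2", w[1], height / 2, width / 2)
  add("stage1 /4", w[2], height / 4, width / 4)
  add("stage2 /8 (P3)", w[3], height / 8, width / 8)
  add("stage3 /16 (P4)", w[4], height / 16, width / 16)
  add("stage4 /32 (P5)", w[5], height / 32, width / 32)
  for (i in 1:3)
    add(sprintf("neck P%d", i + 2), nw, height / 2^(i + 2), width / 2^(i + 2))
  for (i in 1:3)
    add(sprintf("head P%d", i + 2), head_output_width(head),
        height / 2^(i + 2), width / 2^(i + 2))
  do.call(rbind, rows)
}

#' Report the assembled model size
#'
#' Prints per-module and total parameter counts; the total is also returned
#' (in raw scalars). Published counts for comparable lightweight keypoint
#' detectors sit near 2.9 M at full width; exact widths being
#' configuration-dependent, the comparison is diagnostic only.
#'
#' @param model an `sf_net`.
#' @return named list of per-module counts plus `total`, invisibly.
#' @export
inspect_model <- function(model) {
  stopifnot(inherits(model, "sf_net"))
  counts <- vapply(model$modules, count_parameters, numeric(1))
  total <- sum(counts)
  for (nm in names(counts))
    cat(sprintf("  %-8s %12s\n", nm, format(counts[[nm]], big.mark = ",")))
  cat(sprintf("  total    %12s (%.2f M)\n", format(total, big.mark = ","),
              total / 1e6))
  invisible(c(as.list(counts), list(total = total)))
}
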