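# Minimal neural-network layer framework on base-R 4D arrays.
#
# Tensors are arrays with dim (batch, channels, height, width). Modules are
# lists with `$params` (named numeric arrays, the trainable scalars),
# `$modules` (named submodules) and `$meta` (static configuration); forward
# passes are plain R implementations, sufficient for the structural
# contracts this package tests (shapes, gating, residuals, parameter
# counts). Training is out of scope by design.

sf_module <- function(class, params = list(), modules = list(), meta = list()) {
  structure(list(params = params, modules = modules, meta = meta),
            class = c(class, "sf_module"))
}

#' Forward pass of an architecture module
#'
#' @param m a module (conv, block, neck, head or assembled model).
#' @param x input array with dim (batch, channels, height, width), or a
#'   list of such arrays for multi-scale modules.
#' @param ... unused.
#' @return output array (or list of arrays).
#' @export
forward <- function(m, x, ...) UseMethod("forward")

#' Count trainable parameters
#'
#' Exact count of trainable scalars of a module and all its submodules.
#'
#' @param m a module.
#' @return integer count.
#' @examples
#' count_parameters(nn_conv2d(4, 8, kernel = 3))  # 4*8*9 + 8 = 296
#' @export
count_parameters <- function(m) {
  stopifnot(inherits(m, "sf_module"))
  own <- sum(vapply(m$params, length, integer(1)))
  sub <- sum(vapply(m$modules, count_parameters, numeric(1)))
  as.integer(own + sub)
}

#' @export
print.sf_module <- function(x, ...) {
  cat(sprintf("<%s> %s params\n", class(x)[1],
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

check_channels <- function(x, expected, who) {
  if (dim(x)[2] != expected)
    stopf("%s expects %d input channels, got %d", who, expected, dim(x)[2],
          class = "config_error")
}

# ---- primitive layers ------------------------------------------------------

#' 2D convolution layer
#'
#' Standard or grouped/depthwise convolution with "same" padding for odd
#' kernels. Weights are He-initialized from the current RNG state, so a
#' fixed seed yields identical parameters.
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel odd kernel size.
#' @param stride stride (output is subsampled).
#' @param groups convolution groups; `groups = in_channels` with
#'   `out_channels = in_channels` is a depthwise convolution.
#' @param bias include a bias term.
#' @return an `sf_conv2d` module.
#' @export
nn_conv2d <- function(in_channels, out_channels, kernel = 1, stride = 1,
                      groups = 1, bias = TRUE) {
  if (in_channels %% groups != 0 || out_channels %% groups != 0)
    stopf("channels must be divisible by groups", class = "config_error")
  fan_in <- (in_channels / groups) * kernel^2
  w <- array(stats::rnorm(out_channels * (in_channels / groups) * kernel^2,
                          sd = sqrt(2 / fan_in)),
             dim = c(out_channels, in_channels / groups, kernel, kernel))
  params <- list(weight = w)
  if (bias) params$bias <- numeric(out_channels)
  sf_module("sf_conv2d", params = params,
            meta = list(in_channels = in_channels, out_channels = out_channels,
                        kernel = kernel, stride = stride, groups = groups,
                        bias = bias))
}

#' @export
forward.sf_conv2d <- function(m, x, ...) {
  meta <- m$meta
  check_channels(x, meta$in_channels, "conv2d")
  B <- dim(x)[1]; H <- dim(x)[3]; W <- dim(x)[4]
  k <- meta$kernel; s <- meta$stride; p <- (k - 1) %/% 2
  Ho <- (H + 2 * p - k) %/% s + 1L
  Wo <- (W + 2 * p - k) %/% s + 1L
  cin_g <- meta$in_channels / meta$groups
  cout_g <- meta$out_channels / meta$groups
  xp <- array(0, c(B, meta$in_channels, H + 2 * p, W + 2 * p))
  xp[, , p + seq_len(H), p + seq_len(W)] <- x
  out <- array(0, c(B, meta$out_channels, Ho, Wo))
  for (b in seq_len(B)) {
    for (g in seq_len(meta$groups)) {
      ci <- (g - 1) * cin_g + seq_len(cin_g)
      co <- (g - 1) * cout_g + seq_len(cout_g)
      acc <- matrix(0, cout_g, Ho * Wo)
      for (kh in seq_len(k)) {
        rows <- seq.int(kh, by = s, length.out = Ho)
        for (kw in seq_len(k)) {
          cols <- seq.int(kw, by = s, length.out = Wo)
          xs <- matrix(xp[b, ci, rows, cols, drop = FALSE], cin_g, Ho * Wo)
          wm <- matrix(m$params$weight[co, , kh, kw, drop = FALSE], cout_g, cin_g)
          acc <- acc + wm %*% xs
        }
      }
      if (meta$bias) acc <- acc + m$params$bias[co]
      out[b, co, , ] <- acc
    }
  }
  out
}

#' Batch normalization (inference form)
#'
#' Per-channel affine normalization using stored running statistics
#' (initialized to mean 0, variance 1); gamma and beta are the trainable
#' scalars.
#'
#' @param channels channel count.
#' @param eps numerical floor for the variance.
#' @return an `sf_batchnorm` module.
#' @export
nn_batchnorm2d <- function(channels, eps = 1e-5) {
  sf_module("sf_batchnorm",
            params = list(gamma = rep(1, channels), beta = numeric(channels)),
            meta = list(channels = channels, eps = eps,
                        running_mean = numeric(channels),
                        running_var = rep(1, channels)))
}

#' @export
forward.sf_batchnorm <- function(m, x, ...) {
  check_channels(x, m$meta$channels, "batchnorm")
  scale <- m$params$gamma / sqrt(m$meta$running_var + m$meta$eps)
  shift <- m$params$beta - m$meta$running_mean * scale
  out <- x
  for (c in seq_len(m$meta$channels))
    out[, c, , ] <- x[, c, , ] * scale[c] + shift[c]
  out
}

silu <- function(x) x / (1 + exp(-x))
sigmoid <- function(x) 1 / (1 + exp(-x))

apply_activation <- function(x, name) {
  switch(name,
         silu = silu(x), sigmoid = sigmoid(x), relu = pmax(x, 0),
         identity = x,
         stopf("unknown activation '%s'", name, class = "config_error"))
}

upsample2x <- function(x) {
  d <- dim(x)
  x[, , rep(seq_len(d[3]), each = 2), rep(seq_len(d[4]), each = 2), drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[3] == db[3], da[4] == db[4])
  out <- array(0, c(da[1], da[2] + db[2], da[3], da[4]))
  out[, seq_len(da[2]), , ] <- a
  out[, da[2] + seq_len(db[2]), , ] <- b
  out
}

# Conv + BN + SiLU, the YOLO-family "Conv" unit.
nn_conv_unit <- function(in_channels, out_channels, kernel = 3, stride = 1,
                         groups = 1, activation = "silu") {
  sf_module("sf_conv_unit",
            modules = list(conv = nn_conv2d(in_channels, out_channels, kernel,
                                            stride, groups, bias = FALSE),
                           bn = nn_batchnorm2d(out_channels)),
            meta = list(in_channels = in_channels, out_channels = out_channels,
                        stride = stride, activation = activation))
}

#' @export
forward.sf_conv_unit <- function(m, x, ...) {
  apply_activation(forward(m$modules$bn, forward(m$modules$conv, x)),
                   m$meta$activation)
}
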