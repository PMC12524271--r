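# Native CART regression trees for the mass model.
#
# Splits minimize the sum of squared errors (variance reduction), with
# candidate thresholds at midpoints of sorted unique feature values and a
# random subset of `mtry` features considered per node (random subspace
# method). Ties are broken deterministically: lowest feature index, then
# smallest threshold. All randomness comes from the caller's RNG state.

grow_tree <- function(X, y, mtry, min_samples_leaf, max_depth, depth = 0L) {
  n <- length(y)
  if (n < 2L * min_samples_leaf || depth >= max_depth ||
      max(y) - min(y) < .Machine$double.eps * max(1, abs(y[1])) * 8) {
    return(list(leaf = TRUE, value = mean(y), n = n))
  }
  feats <- sort(sample.int(ncol(X), min(mtry, ncol(X))))
  best <- NULL
  for (j in feats) {
    x <- X[, j]
    ord <- order(x, method = "radix")
    xs <- x[ord]; ys <- y[ord]
    # valid split positions: after index i, both sides hold >= min_samples_leaf
    # and the feature value actually changes across the boundary
    i <- seq_len(n - 1L)
    ok <- i >= min_samples_leaf & i <= n - min_samples_leaf & xs[i] < xs[i + 1L]
    if (!any(ok)) next
    csum <- cumsum(ys); tot <- csum[n]
    csq <- cumsum(ys^2)
    # SSE_left + SSE_right = sum(y^2) - meanL^2*nL - meanR^2*nR (up to const)
    nl <- i; nr <- n - i
    gain <- csum[i]^2 / nl + (tot - csum[i])^2 / nr  # maximize
    gain[!ok] <- -Inf
    k <- which.max(gain)
    if (gain[k] > tot^2 / n + 1e-12 * abs(tot^2 / n + 1)) {
      # features are visited in ascending index and which.max() takes the
      # smallest qualifying threshold, so keeping strict improvements only
      # realizes the documented tie-break (lowest feature, then threshold)
      if (is.null(best) || gain[k] > best$gain + 1e-12)
        best <- list(feature = j, threshold = (xs[k] + xs[k + 1L]) / 2,
                     gain = gain[k])
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, value = mean(y), n = n))
  go_left <- X[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_tree(X[go_left, , drop = FALSE], y[go_left], mtry,
                        min_samples_leaf, max_depth, depth + 1L),
       right = grow_tree(X[!go_left, , drop = FALSE], y[!go_left], mtry,
                         min_samples_leaf, max_depth, depth + 1L))
}

predict_tree <- function(node, X) {
  n <- nrow(X)
  out <- numeric(n)
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$value; return() }
    left <- X[idx, node$feature] <= node$threshold
    rec(node$left, idx[left])
    rec(node$right, idx[!left])
  }
  rec(node, seq_len(n))
  out
}

tree_depth <- function(node) {
  if (node$leaf) 0L else 1L + max(tree_depth(node$left), tree_depth(node$right))
}

tree_n_leaves <- function(node) {
  if (node$leaf) 1L else tree_n_leaves(node$left) + tree_n_leaves(node$right)
}
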