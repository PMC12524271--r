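#' Random-forest regression of fish mass on body size
#'
#' Fits an ensemble of CART regression trees mapping body length and width
#' (cm) to body mass (g), the allometric stage of the size-and-mass
#' pipeline. Each tree is grown on a bootstrap resample of the data (same
#' size, with replacement) with variance-reduction splits restricted to a
#' random subset of `mtry` features per node; the forest prediction is the
#' arithmetic mean of the tree predictions, and is therefore always bounded
#' by the range of the training response.
#'
#' Typical use fits on caliper-measured sizes and masses and predicts from
#' stereo-estimated sizes. With only two features the random subspace step
#' is nearly degenerate; `mtry = 1` still decorrelates trees and is the
#' default.
#'
#' @param formula model formula, e.g. `mass_g ~ length_cm + width_cm`
#'   (numeric predictors only).
#' @param data data frame of training samples (>= 2 rows, all finite).
#' @param n_trees number of trees.
#' @param mtry features considered per split.
#' @param min_samples_leaf minimum training samples per leaf.
#' @param max_depth maximum tree depth (`Inf` = fully grown).
#' @param bootstrap draw a bootstrap resample per tree (TRUE) or fit every
#'   tree on the full sample (FALSE).
#' @param seed integer; the fit is deterministic given data and seed.
#' @return an object of class `mass_forest` with `print`, `summary`,
#'   `predict`, `fitted` and `residuals` methods.
#' @examples
#' d <- data.frame(length_cm = c(10, 12, 15, 17, 9, 14),
#'                 width_cm  = c(2.5, 2.8, 3.2, 4.0, 2.2, 3.1),
#'                 mass_g    = c(19, 35, 63, 99, 13, 55))
#' fit <- mass_forest(mass_g ~ length_cm + width_cm, d, n_trees = 25, seed = 1)
#' predict(fit, data.frame(length_cm = 13, width_cm = 3.0))
#' @export
mass_forest <- function(formula = mass_g ~ length_cm + width_cm, data,
                        n_trees = 100, mtry = 1, min_samples_leaf = 2,
                        max_depth = Inf, bootstrap = TRUE, seed = 1) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- as.matrix(mf[, -1, drop = FALSE])
  n <- length(y)
  if (n < 2) stopf("need at least 2 samples", class = "config_error")
  if (n < min_samples_leaf)
    stopf("fewer samples (%d) than min_samples_leaf (%d)", n, min_samples_leaf,
          class = "config_error")
  check_finite(X, "predictors"); check_finite(y, "response")
  if (mtry < 1 || mtry > ncol(X))
    stopf("mtry must be in [1, %d]", ncol(X), class = "config_error")
  trees <- vector("list", n_trees)
  with_seed(seed, {
    for (t in seq_len(n_trees)) {
      idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      trees[[t]] <- grow_tree(X[idx, , drop = FALSE], y[idx], mtry = mtry,
                              min_samples_leaf = min_samples_leaf,
                              max_depth = max_depth)
    }
  })
  obj <- structure(list(
    trees = trees,
    config = list(n_trees = n_trees, mtry = mtry,
                  min_samples_leaf = min_samples_leaf,
                  max_depth = max_depth, bootstrap = bootstrap),
    seed = seed,
    features = colnames(X),
    response = deparse(formula[[2]]),
    y_range = range(y),
    formula = formula,
    n_train = n,
    call = match.call()), class = "mass_forest")
  obj$train_fitted <- predict(obj, stats::setNames(as.data.frame(X), obj$features))
  obj$train_response <- as.numeric(y)
  obj
}

#' @export
print.mass_forest <- function(x, ...) {
  cat("Random-forest mass model (native CART ensemble)\n")
  cat(sprintf("  %d trees, mtry = %d, min leaf = %d, %s, bootstrap = %s\n",
              x$config$n_trees, x$config$mtry, x$config$min_samples_leaf,
              if (is.finite(x$config$max_depth))
                sprintf("max depth = %d", x$config$max_depth) else "fully grown",
              x$config$bootstrap))
  cat(sprintf("  trained on %d fish; response %s in [%.1f, %.1f] g\n",
              x$n_train, x$response, x$y_range[1], x$y_range[2]))
  invisible(x)
}

#' @export
summary.mass_forest <- function(object, ...) {
  res <- stats::residuals(object)
  depths <- vapply(object$trees, tree_depth, integer(1))
  leaves <- vapply(object$trees, tree_n_leaves, integer(1))
  out <- list(model = object,
              train_metrics = regression_metrics(object$train_response,
                                                 object$train_fitted),
              mean_depth = mean(depths), mean_leaves = mean(leaves),
              residual_sd = stats::sd(res))
  class(out) <- "summary.mass_forest"
  out
}

#' @export
print.summary.mass_forest <- function(x, ...) {
  print(x$model)
  m <- x$train_metrics
  cat(sprintf("  trees: mean depth %.1f, mean leaves %.1f\n",
              x$mean_depth, x$mean_leaves))
  cat(sprintf("  in-sample: MAE %.3f g, RMSE %.3f g, R2 %.4f\n",
              m$MAE, m$RMSE, m$R2))
  invisible(x)
}

#' Predict fish mass
#'
#' @param object a fitted [mass_forest()].
#' @param newdata data frame carrying the model's feature columns.
#' @param ... unused.
#' @return numeric vector of predicted masses (g), the arithmetic mean over
#'   all trees.
#' @export
predict.mass_forest <- function(object, newdata, ...) {
  if (is.null(object$trees) || !length(object$trees))
    stopf("model has no trees; not fitted?", class = "state_error")
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) stopf("newdata lacks columns: %s", paste(miss, collapse = ", "),
                          class = "schema_error")
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  check_finite(X, "predictors")
  preds <- vapply(object$trees, function(tr) predict_tree(tr, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) mean(preds) else rowMeans(preds)
}

#' @export
fitted.mass_forest <- function(object, ...) object$train_fitted

#' @export
residuals.mass_forest <- function(object, ...)
  object$train_response - object$train_fitted

#' Predict mass from length and width
#'
#' Convenience wrapper around [predict.mass_forest()] for scalar or vector
#' size estimates.
#'
#' @param model fitted [mass_forest()] with features `length_cm`, `width_cm`.
#' @param length_cm,width_cm sizes in centimeters.
#' @return predicted mass in grams.
#' @export
predict_mass <- function(model, length_cm, width_cm)
  predict(model, data.frame(length_cm = length_cm, width_cm = width_cm))

# ---- serialization ---------------------------------------------------------

forest_version <- "stereofish-forest/1"

node_to_list <- function(node) {
  if (node$leaf) list(leaf = TRUE, value = node$value, n = node$n)
  else list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
            left = node_to_list(node$left), right = node_to_list(node$right))
}

node_from_list <- function(l) {
  if (isTRUE(l$leaf)) list(leaf = TRUE, value = l$value, n = as.integer(l$n))
  else list(leaf = FALSE, feature = as.integer(l$feature), threshold = l$threshold,
            left = node_from_list(l$left), right = node_from_list(l$right))
}

#' Save / load a fitted mass model as versioned JSON
#'
#' Trees are stored as nested objects so fitted models are portable across
#' machines and sessions without binary formats.
#'
#' @param model fitted [mass_forest()].
#' @param path JSON file path.
#' @return `path` invisibly (write); a `mass_forest` (read).
#' @export
write_mass_model <- function(model, path) {
  stopifnot(inherits(model, "mass_forest"))
  j <- list(format = forest_version,
            config = model$config, seed = model$seed,
            features = model$features, response = model$response,
            y_range = model$y_range, n_train = model$n_train,
            trees = lapply(model$trees, node_to_list))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mass_model
#' @export
read_mass_model <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(j$format, forest_version))
    stopf("unsupported model format: %s", j$format, class = "io_error")
  structure(list(trees = lapply(j$trees, node_from_list),
                 config = j$config, seed = j$seed,
                 features = unlist(j$features), response = j$response,
                 y_range = unlist(j$y_range), n_train = j$n_train,
                 train_fitted = NULL, train_response = NULL),
            class = "mass_forest")
}

# ---- regressor registry and comparison ------------------------------------

.regressors <- new.env(parent = emptyenv())

#' Register a regressor for model comparison
#'
#' [compare_regressors()] evaluates any regressor registered here next to
#' the native forest. A regressor is a pair of closures: `fit(train)` and
#' `predict(fit_result, test)`, both working on data frames with columns
#' `length_cm`, `width_cm`, `mass_g`.
#'
#' @param name registry key.
#' @param fit,predict closures as described above.
#' @return `name`, invisibly.
#' @export
register_regressor <- function(name, fit, predict) {
  assign(name, list(fit = fit, predict = predict), envir = .regressors)
  invisible(name)
}

#' @rdname register_regressor
#' @export
list_regressors <- function() sort(ls(.regressors))

default_regressors <- function() {
  register_regressor("forest",
    fit = function(train) mass_forest(mass_g ~ length_cm + width_cm, train,
                                      seed = 1),
    predict = function(m, test) predict(m, test))
  register_regressor("linear",
    fit = function(train) stats::lm(mass_g ~ length_cm + width_cm, train),
    predict = function(m, test) as.numeric(stats::predict(m, test)))
}

#' Compare mass regressors on a held-out split
#'
#' One shuffled train/test split (fixed by `seed`), the native forest plus
#' any registered competitors, scored with [regression_metrics()].
#'
#' @param data data frame with `length_cm`, `width_cm`, `mass_g` (>= 10 rows).
#' @param models registry names to evaluate (default: all registered).
#' @param split_fraction fraction of rows used for training, in (0, 1).
#' @param seed split seed.
#' @return data.frame with one row per model: MAE, MSE, RMSE, R2.
#' @export
compare_regressors <- function(data, models = list_regressors(),
                               split_fraction = 0.8, seed = 1) {
  if (nrow(data) < 10) stopf("need >= 10 samples", class = "config_error")
  if (split_fraction <= 0 || split_fraction >= 1)
    stopf("split_fraction must be in (0, 1): an empty train or test set is not evaluable",
          class = "config_error")
  unknown <- setdiff(models, list_regressors())
  if (length(unknown))
    stopf("unknown regressor(s): %s", paste(unknown, collapse = ", "),
          class = "registry_error")
  n <- nrow(data)
  idx <- with_seed(seed, sample.int(n))
  n_train <- floor(n * split_fraction)
  if (n_train < 1 || n_train >= n)
    stopf("split leaves an empty train or test set", class = "config_error")
  train <- data[idx[seq_len(n_train)], ]
  test <- data[idx[(n_train + 1):n], ]
  rows <- lapply(models, function(nm) {
    reg <- get(nm, envir = .regressors)
    m <- reg$fit(train)
    pred <- reg$predict(m, test)
    met <- regression_metrics(test$mass_g, pred)
    data.frame(model = nm, MAE = met$MAE, MSE = met$MSE, RMSE = met$RMSE,
               R2 = met$R2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
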