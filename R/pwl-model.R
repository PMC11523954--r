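#' Training configuration for the point-wise linear model
#'
#' @param depth Number of hidden layers of the weight-generator network.
#' @param width Neurons per hidden layer.
#' @param learning_rate Adam learning rate.
#' @param epochs Maximum full-batch epochs.
#' @param weight_decay L2 penalty on all network weight matrices.
#' @param lambda_w Optional L2 penalty on the *emitted* per-sample weight
#'   vectors (0 disables it; a small value stabilizes small-n fits).
#' @param holdout Fraction of training samples held out internally for
#'   early stopping (0 disables early stopping).
#' @param patience Epochs without holdout improvement before stopping.
#' @param seed Master seed for initialization, holdout split and folds.
#' @return A list of class `pwl_config`.
#' @export
pwl_config <- function(depth = 3L, width = 64L, learning_rate = 1e-3,
                       epochs = 500L, weight_decay = 1e-4, lambda_w = 0,
                       holdout = 0.2, patience = 50L, seed = 1L) {
  structure(list(
    depth = as.integer(depth), width = as.integer(width),
    learning_rate = learning_rate, epochs = as.integer(epochs),
    weight_decay = weight_decay, lambda_w = lambda_w,
    holdout = holdout, patience = as.integer(patience),
    seed = check_seed(seed)
  ), class = "pwl_config")
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.numeric(X)) {
    abort("Features must be numeric.", class = "pwlscore_validation_error")
  }
  if (any(!is.finite(X))) {
    abort("Features contain non-finite values; preprocess first.",
          class = "pwlscore_validation_error")
  }
  X
}

check_labels <- function(y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    abort("Labels must be binary 0/1.", class = "pwlscore_validation_error")
  }
  if (length(unique(y)) < 2) {
    abort("Both classes must be present.",
          class = "pwlscore_degenerate_labels")
  }
  y
}

#' Fit a point-wise linear (PWL) model
#'
#' Trains the weight-generator network by minimizing the mean binary
#' cross-entropy of \eqn{\sigma(w(x)^\top x + b(x))} plus an L2 penalty on
#' the network parameters, using full-batch Adam with an internal
#' early-stopping holdout. The result is a per-sample logistic model: for
#' every input the network emits a tailored weight vector and intercept.
#'
#' @param X Preprocessed feature matrix or data frame (no missing values;
#'   see [apply_preprocess()]).
#' @param y Binary labels (0/1), both classes present.
#' @param config A [pwl_config()].
#' @return A `pwl_model` object.
#' @examples
#' \donttest{
#' X <- matrix(rnorm(200 * 4), 200, 4)
#' y <- rbinom(200, 1, plogis(2 * X[, 1]))
#' fit <- fit_pwl(X, y, pwl_config(epochs = 100, seed = 1))
#' head(predict_proba(fit, X))
#' }
#' @export
fit_pwl <- function(X, y, config = pwl_config()) {
  X <- as_feature_matrix(X)
  y <- check_labels(y)
  if (nrow(X) != length(y)) {
    abort("`X` and `y` sizes differ.", class = "pwlscore_dimension_error")
  }
  stopifnot(inherits(config, "pwl_config"))

  res <- withr::with_seed(config$seed, pwl_train(X, y, config))

  structure(list(
    params = res$params,
    d = ncol(X),
    feature_names = colnames(X),
    config = config,
    history = res$history,
    best_epoch = res$best_epoch,
    holdout_loss = res$holdout_loss,
    n = nrow(X)
  ), class = "pwl_model")
}

check_pwl_input <- function(model, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != model$d) {
    abort(sprintf("Model expects %d features, got %d.", model$d, ncol(X)),
          class = "pwlscore_dimension_error")
  }
  X
}

#' Predict responder probabilities from a PWL model
#'
#' Computes \eqn{p_j = \sigma(w_j^\top x_j + b_j)} where \eqn{(w_j, b_j)}
#' is the weight vector the generator network emits for sample \eqn{j}.
#' Identical inputs always produce identical outputs.
#'
#' @param model A fitted `pwl_model`.
#' @param X Preprocessed feature matrix with the training dimension.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, X) {
  UseMethod("predict_proba")
}

#' @export
predict_proba.pwl_model <- function(model, X) {
  X <- check_pwl_input(model, X)
  pwl_forward(model$params, X)$p
}

#' @export
predict.pwl_model <- function(object, newdata, ...) {
  predict_proba(object, newdata)
}

#' Extract per-sample logistic weight vectors
#'
#' Returns the weight vector and intercept the generator emits for each
#' sample — the sample-tailored linear model behind each prediction, and
#' the raw material of the importance-score procedure.
#'
#' @param model A fitted `pwl_model`.
#' @param X Preprocessed feature matrix.
#' @return A `sample_weights` object: list with `weights` (samples x
#'   features matrix), `intercept` (vector), `features`. Its [tidy()]
#'   method returns a long tibble.
#' @export
extract_weights <- function(model, X) {
  X <- check_pwl_input(model, X)
  fwd <- pwl_forward(model$params, X)
  W <- fwd$w
  colnames(W) <- model$feature_names
  structure(list(weights = W, intercept = fwd$b,
                 features = model$feature_names),
            class = "sample_weights")
}

#' @export
print.sample_weights <- function(x, ...) {
  cat("<sample_weights>", nrow(x$weights), "samples x",
      ncol(x$weights), "features\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sample_weights <- function(x, ...) {
  W <- x$weights
  tibble::tibble(
    sample = rep(seq_len(nrow(W)), times = ncol(W)),
    feature = rep(colnames(W) %||% paste0("x", seq_len(ncol(W))),
                  each = nrow(W)),
    weight = as.vector(W)
  )
}

#' @export
print.pwl_model <- function(x, ...) {
  cat("<pwl_model> d =", x$d, "| depth", x$config$depth,
      "x width", x$config$width, "| trained", length(x$history),
      "epochs (best", x$best_epoch, ")\n")
  invisible(x)
}

#' Tidy a fitted PWL model into per-feature summaries
#'
#' Summarizes the per-sample weight vectors on the data the model was
#' asked about: the median sample-wise weight and its sign per feature.
#'
#' @param x A `pwl_model`.
#' @param X Feature matrix to summarize over (typically the discovery set).
#' @param ... Unused.
#' @return Tibble with `feature`, `median_weight`, `sign`.
#' @exportS3Method generics::tidy
tidy.pwl_model <- function(x, X, ...) {
  sw <- extract_weights(x, X)
  med <- apply(sw$weights, 2, median)
  tibble::tibble(
    feature = x$feature_names %||% paste0("x", seq_len(x$d)),
    median_weight = unname(med),
    sign = sign(unname(med))
  )
}

#' @exportS3Method generics::glance
glance.pwl_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, d = x$d,
    epochs_run = length(x$history),
    best_epoch = x$best_epoch,
    final_train_loss = x$history[length(x$history)],
    holdout_loss = x$holdout_loss
  )
}

#' Select PWL hyper-parameters by stratified k-fold cross-validation
#'
#' For every row of `grid` (columns override [pwl_config()] fields),
#' trains on k-1 folds and scores AUC on the held-out fold; the selected
#' point is the one with the highest mean fold AUC (ties broken by grid
#' order). The fold partition is stratified and derived from `seed`, so
#' baseline models can reuse the identical partition.
#'
#' @param X,y As in [fit_pwl()].
#' @param grid Data frame of hyper-parameter combinations; default crosses
#'   weight decay \{1e-4, 1e-3, 1e-2\} with depth \{2, 3\}.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold partition.
#' @param config Base configuration the grid rows override.
#' @return A `cv_result`: tibble `grid` with `mean_auc` and `fold_aucs`
#'   (list column), `best` row index, `folds` assignment, `k`, `seed`.
#' @export
select_hyperparams_cv <- function(X, y,
                                  grid = expand.grid(
                                    weight_decay = c(1e-4, 1e-3, 1e-2),
                                    depth = c(2L, 3L)),
                                  k = 5L, seed = 1L,
                                  config = pwl_config()) {
  X <- as_feature_matrix(X)
  y <- check_labels(y)
  if (nrow(X) < k) {
    abort("Fewer samples than folds.", class = "pwlscore_invalid_parameter")
  }
  if (nrow(grid) == 0) {
    abort("Empty hyper-parameter grid.",
          class = "pwlscore_invalid_parameter")
  }
  folds <- make_stratified_folds(y, k = k, seed = seed)

  fold_aucs <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][g]
    cfg$seed <- check_seed(seed)
    aucs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- fit_pwl(X[tr, , drop = FALSE], y[tr], cfg)
      auc(predict_proba(fit, X[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    fold_aucs[[g]] <- aucs
  }
  res <- tibble::as_tibble(grid)
  res$fold_aucs <- fold_aucs
  res$mean_auc <- vapply(fold_aucs, mean, numeric(1))
  structure(list(grid = res, best = which.max(res$mean_auc),
                 folds = folds, k = k, seed = check_seed(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", nrow(x$grid), "grid points,", x$k, "folds; best row",
      x$best, "(mean AUC", round(x$grid$mean_auc[x$best], 3), ")\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) {
  out <- x$grid
  out$selected <- seq_len(nrow(out)) == x$best
  out
}

#' Serialize / restore a fitted PWL model as JSON
#'
#' The checkpoint embeds the full parameter set, configuration and seed.
#'
#' @param model A `pwl_model`.
#' @param path File path.
#' @export
write_pwl_model <- function(model, path) {
  stopifnot(inherits(model, "pwl_model"))
  payload <- list(
    d = model$d, feature_names = model$feature_names,
    config = unclass(model$config),
    history = model$history, best_epoch = model$best_epoch, n = model$n,
    holdout_loss = model$holdout_loss,
    params = list(
      W = lapply(model$params$W, function(m) list(dim = dim(m),
                                                  x = as.vector(m))),
      b = model$params$b,
      Wo = list(dim = dim(model$params$Wo), x = as.vector(model$params$Wo)),
      bo = model$params$bo
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pwl_model
#' @export
read_pwl_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  rebuild <- function(m) matrix(unlist(m$x), unlist(m$dim)[1], unlist(m$dim)[2])
  params <- list(
    W = lapply(p$params$W, rebuild),
    b = lapply(p$params$b, unlist),
    Wo = rebuild(p$params$Wo),
    bo = unlist(p$params$bo)
  )
  cfg <- do.call(pwl_config, p$config)
  structure(list(
    params = params, d = p$d, feature_names = unlist(p$feature_names),
    config = cfg, history = unlist(p$history), best_epoch = p$best_epoch,
    holdout_loss = p$holdout_loss, n = p$n
  ), class = "pwl_model")
}
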