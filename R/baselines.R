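#' Fit a baseline comparator model under the shared CV protocol
#'
#' Two comparators are supported:
#' \describe{
#'   \item{`elastic_net_lr`}{logistic regression with elastic-net penalty
#'     \eqn{\alpha(\rho \|\beta\|_1 + (1-\rho)/2 \|\beta\|_2^2)}, fitted by
#'     \pkg{glmnet} (`strength` maps to glmnet's lambda and `mixing` to its
#'     alpha);}
#'   \item{`gradient_boosting`}{staged regression trees on logistic loss,
#'     fitted by \pkg{xgboost}.}
#' }
#' The best grid row is chosen by mean held-out AUC over stratified k-fold
#' cross-validation; with the same `seed`, the fold partition is identical
#' to the one [select_hyperparams_cv()] builds for the PWL model, so
#' discovery-cohort metrics are head-to-head comparable. The returned model
#' is refitted on the full data at the selected point.
#'
#' @param kind `"elastic_net_lr"` or `"gradient_boosting"`.
#' @param X Preprocessed feature matrix (no missing values).
#' @param y Binary labels (0/1).
#' @param grid Hyper-parameter data frame. Defaults: elastic net crosses
#'   `strength` \{0.001, 0.01, 0.1, 1\} with `mixing` \{0.2, 0.5, 0.8\};
#'   boosting crosses `max_depth` \{2, 3\}, `nrounds` \{50, 200\} and
#'   `learning_rate` \{0.05, 0.1\}.
#' @param k Folds (default 5).
#' @param seed Integer seed (folds + fit determinism).
#' @return A `baseline_model` with the CV record in `$cv`.
#' @export
fit_baseline <- function(kind = c("elastic_net_lr", "gradient_boosting"),
                         X, y, grid = NULL, k = 5L, seed = 1L) {
  kind <- match.arg(kind)
  X <- as_feature_matrix(X)
  y <- check_labels(y)
  seed <- check_seed(seed)

  if (is.null(grid)) {
    grid <- if (kind == "elastic_net_lr") {
      expand.grid(strength = c(0.001, 0.01, 0.1, 1),
                  mixing = c(0.2, 0.5, 0.8))
    } else {
      expand.grid(max_depth = c(2L, 3L), nrounds = c(50L, 200L),
                  learning_rate = c(0.05, 0.1))
    }
  }

  folds <- make_stratified_folds(y, k = k, seed = seed)
  fold_aucs <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    row <- grid[g, , drop = FALSE]
    aucs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- baseline_engine(kind, X[tr, , drop = FALSE], y[tr], row, seed)
      auc(baseline_predict(fit, X[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    fold_aucs[[g]] <- aucs
  }
  cv <- tibble::as_tibble(grid)
  cv$fold_aucs <- fold_aucs
  cv$mean_auc <- vapply(fold_aucs, mean, numeric(1))
  best <- which.max(cv$mean_auc)

  final <- baseline_engine(kind, X, y, grid[best, , drop = FALSE], seed)
  structure(list(kind = kind, fit = final,
                 cv = list(grid = cv, best = best, folds = folds,
                           k = k, seed = seed),
                 feature_names = colnames(X), d = ncol(X)),
            class = "baseline_model")
}

baseline_engine <- function(kind, X, y, row, seed) {
  if (kind == "elastic_net_lr") {
    fit <- glmnet::glmnet(X, y, family = "binomial",
                          alpha = row$mixing, lambda = row$strength,
                          standardize = FALSE)
    list(engine = fit, row = row)
  } else {
    dm <- xgboost::xgb.DMatrix(X, label = y)
    fit <- withr::with_seed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = row$max_depth, eta = row$learning_rate,
                    nthread = 1, seed = seed),
      data = dm, nrounds = row$nrounds, verbose = 0))
    list(engine = fit, row = row)
  }
}

baseline_predict <- function(fit, X) {
  if (inherits(fit$engine, "glmnet")) {
    as.numeric(predict(fit$engine, newx = X, type = "response",
                       s = fit$row$strength))
  } else {
    as.numeric(predict(fit$engine, xgboost::xgb.DMatrix(X)))
  }
}

#' @export
predict_proba.baseline_model <- function(model, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != model$d) {
    abort(sprintf("Model expects %d features, got %d.", model$d, ncol(X)),
          class = "pwlscore_dimension_error")
  }
  baseline_predict(model$fit, X)
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  predict_proba(object, newdata)
}

#' @export
print.baseline_model <- function(x, ...) {
  cat("<baseline_model>", x$kind, "| d =", x$d,
      "| CV mean AUC", round(x$cv$grid$mean_auc[x$cv$best], 3), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.baseline_model <- function(x, ...) {
  if (x$kind == "elastic_net_lr") {
    b <- as.matrix(stats::coef(x$fit$engine, s = x$fit$row$strength))
    tibble::tibble(feature = rownames(b), estimate = as.numeric(b))
  } else {
    imp <- xgboost::xgb.importance(model = x$fit$engine)
    tibble::tibble(feature = imp$Feature, estimate = imp$Gain)
  }
}

#' @exportS3Method generics::glance
glance.baseline_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    cv_mean_auc = x$cv$grid$mean_auc[x$cv$best],
    n_grid = nrow(x$cv$grid), k = x$cv$k
  )
}
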