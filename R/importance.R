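#' Sample-wise feature importance from per-sample weight vectors
#'
#' The importance of feature i for sample j is the absolute value of that
#' sample's emitted weight, `|w_ji|` (`mode = "weight"`, the default).
#' `mode = "weight_x"` instead uses `|w_ji * x_ji|`, weighting by the
#' realized feature value.
#'
#' @param weights A `sample_weights` object from [extract_weights()], or a
#'   samples x features numeric matrix.
#' @param X Feature matrix; required only for `mode = "weight_x"`.
#' @param mode `"weight"` or `"weight_x"`.
#' @return Samples x features matrix of non-negative importances.
#' @export
sample_importance <- function(weights, X = NULL,
                              mode = c("weight", "weight_x")) {
  mode <- match.arg(mode)
  W <- if (inherits(weights, "sample_weights")) weights$weights else
    as.matrix(weights)
  if (any(!is.finite(W))) {
    abort("Weights must be finite.", class = "pwlscore_validation_error")
  }
  if (mode == "weight_x") {
    if (is.null(X)) {
      abort("`X` is required for mode = \"weight_x\".",
            class = "pwlscore_invalid_parameter")
    }
    W <- W * as_feature_matrix(X)
  }
  abs(W)
}

#' Importance scores by top-decile ranking rate
#'
#' Per sample, features are ranked by their sample-wise importance in
#' descending order (ties broken by stable feature order) and the top
#' `k = max(1, ceiling(top_fraction * d))` features are marked "ranked".
#' The importance score of feature i is the fraction of samples in which i
#' is ranked. A score of 0.1 means at least 10% of samples had the feature
#' in their top 10%.
#'
#' @param sample_imp Samples x features importance matrix from
#'   [sample_importance()].
#' @param top_fraction Fraction of features counted as top-ranked per
#'   sample (default 0.10).
#' @return Tibble with `feature`, `score`, sorted by descending score
#'   (stable); attribute `k` records the per-sample ranked count.
#' @export
importance_scores <- function(sample_imp, top_fraction = 0.10) {
  M <- as.matrix(sample_imp)
  n <- nrow(M)
  d <- ncol(M)
  if (n < 1 || d < 1) {
    abort("Need at least one sample and one feature.",
          class = "pwlscore_invalid_parameter")
  }
  check_fraction(top_fraction, "top_fraction", 0, 1, lo_open = TRUE)
  k <- max(1L, ceiling(top_fraction * d))
  feats <- colnames(M) %||% paste0("x", seq_len(d))

  counts <- integer(d)
  for (j in seq_len(n)) {
    # stable: order() breaks importance ties by original feature position
    top <- order(-M[j, ])[seq_len(k)]
    counts[top] <- counts[top] + 1L
  }
  out <- tibble::tibble(feature = feats, score = counts / n)
  out <- out[order(-out$score), ]
  attr(out, "k") <- k
  out
}

#' Extract important features and their signs
#'
#' Keeps features whose importance score reaches the cutoff (default 0.1,
#' strict `>=`) and assigns each the sign of its median sample-wise weight
#' over the model-building cohort. Features with an exactly zero median
#' weight are dropped with a warning.
#'
#' @param report Importance-score tibble from [importance_scores()].
#' @param median_weights Named numeric vector (or tibble `feature`,
#'   `median_weight`, e.g. from [tidy.pwl_model()]) of median sample-wise
#'   weights.
#' @param cutoff Minimum importance score (default 0.1).
#' @return A `simple_score_model`: tibble `feature`, `score`,
#'   `median_weight`, `sign` for the extracted set, ordered by descending
#'   importance.
#' @export
extract_features <- function(report, median_weights, cutoff = 0.1) {
  if (is.data.frame(median_weights)) {
    median_weights <- setNames(median_weights$median_weight,
                               median_weights$feature)
  }
  kept <- report[report$score >= cutoff, , drop = FALSE]
  kept$median_weight <- unname(median_weights[kept$feature])
  if (anyNA(kept$median_weight)) {
    abort("Median weights missing for some extracted features.",
          class = "pwlscore_schema_error")
  }
  zero <- kept$median_weight == 0
  if (any(zero)) {
    warn(paste0("Dropping features with zero median weight: ",
                paste(kept$feature[zero], collapse = ", ")))
    kept <- kept[!zero, , drop = FALSE]
  }
  if (nrow(kept) == 0) {
    abort("No features pass the importance cutoff.",
          class = "pwlscore_empty_model")
  }
  kept$sign <- sign(kept$median_weight)
  class(kept) <- c("simple_score_model", class(kept))
  kept
}

#' Compute simple prediction scores
#'
#' The simple prediction score of a sample is the signed sum of its
#' extracted features' preprocessed values:
#' \eqn{S_j = \sum_i \sigma_i x_{ji}}, with \eqn{\sigma_i \in \{+1, -1\}}
#' the sign of the feature's median sample-wise weight.
#'
#' @param model A `simple_score_model` from [extract_features()].
#' @param features Preprocessed feature table containing every model
#'   feature (see [apply_preprocess()]).
#' @return Numeric score vector, one per sample.
#' @export
simple_score <- function(model, features) {
  stopifnot(inherits(model, "simple_score_model"))
  missing_feats <- setdiff(model$feature, names(features))
  if (length(missing_feats) > 0) {
    abort(paste0("Features absent from data: ",
                 paste(missing_feats, collapse = ", ")),
          class = "pwlscore_schema_error")
  }
  X <- as.matrix(as.data.frame(features)[, model$feature, drop = FALSE])
  drop(X %*% model$sign)
}

#' @exportS3Method generics::tidy
tidy.simple_score_model <- function(x, ...) {
  tibble::as_tibble(x)[, c("feature", "score", "median_weight", "sign")]
}

#' Divide scores into quartile groups Q1-Q4
#'
#' Samples are ordered by score (ties broken by stable input order) and cut
#' into four contiguous groups of (near-)equal size; Q1 is the lowest
#' quarter. Group sizes differ by at most one (112 samples give 28 per
#' group).
#'
#' @param scores Numeric vector, length >= 4.
#' @return Tibble with `sample` (input position), `score`, `group`
#'   (factor Q1-Q4); per-group score ranges are attached as attribute
#'   `boundaries`.
#' @export
quartile_groups <- function(scores) {
  n <- length(scores)
  if (n < 4) {
    abort("Need at least 4 scores for quartile groups.",
          class = "pwlscore_invalid_parameter")
  }
  ord <- order(scores) # stable: ties keep input order
  grp_sorted <- ceiling(4 * seq_len(n) / n)
  group <- integer(n)
  group[ord] <- grp_sorted
  out <- tibble::tibble(
    sample = seq_len(n), score = scores,
    group = factor(paste0("Q", group), levels = paste0("Q", 1:4))
  )
  attr(out, "boundaries") <- out |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), min = min(.data$score),
                     max = max(.data$score), .groups = "drop")
  out
}
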