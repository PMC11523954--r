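#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' Equivalent to counting concordant score pairs across the two classes,
#' with tied scores counted 1/2.
#'
#' @param scores Numeric prediction scores (higher = more likely positive).
#' @param y Binary labels (0/1); both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
#' @export
auc <- function(scores, y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) {
    abort("AUC needs both classes present.",
          class = "pwlscore_degenerate_labels")
  }
  if (length(scores) != length(y)) {
    abort("`scores` and `y` sizes differ.",
          class = "pwlscore_dimension_error")
  }
  r <- rank(scores, ties.method = "average")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity/specificity at an operating threshold
#'
#' `threshold_rule = "youden"` picks the threshold maximizing Youden's J
#' (sensitivity + specificity − 1) over the observed scores, preferring
#' the lowest such threshold on ties; `"fixed"` classifies at
#' `score >= 0.5`. A sample is predicted positive when its score is at
#' least the threshold.
#'
#' @param scores,y As in [auc()].
#' @param threshold_rule `"youden"` or `"fixed"`.
#' @return Tibble with `auc`, `sensitivity`, `specificity`, `threshold`.
#' @export
classification_metrics <- function(scores, y,
                                   threshold_rule = c("youden", "fixed")) {
  threshold_rule <- match.arg(threshold_rule)
  y <- as.numeric(y)
  a <- auc(scores, y)
  if (threshold_rule == "fixed") {
    thr <- 0.5
  } else {
    cand <- sort(unique(scores))
    j <- vapply(cand, function(t) {
      sens <- mean(scores[y == 1] >= t)
      spec <- mean(scores[y == 0] < t)
      sens + spec - 1
    }, numeric(1))
    thr <- cand[which.max(j)] # which.max takes the first (lowest) on ties
  }
  tibble::tibble(
    auc = a,
    sensitivity = mean(scores[y == 1] >= thr),
    specificity = mean(scores[y == 0] < thr),
    threshold = thr
  )
}

#' Evaluate a fitted model on labeled data
#'
#' Computes AUC by the rank statistic over all class pairs, and
#' sensitivity/specificity at the operating point chosen by
#' `threshold_rule`.
#'
#' @param model A `pwl_model`, `baseline_model`, or a numeric score vector.
#' @param X Feature matrix (ignored when `model` is already scores).
#' @param y Binary labels.
#' @param threshold_rule Passed to [classification_metrics()].
#' @return One-row tibble: `auc`, `sensitivity`, `specificity`, `threshold`.
#' @export
evaluate_model <- function(model, X, y, threshold_rule = "youden") {
  scores <- if (is.numeric(model)) model else predict_scores(model, X)
  classification_metrics(scores, y, threshold_rule)
}

# internal dispatch: probability-scale scores from any supported model
predict_scores <- function(model, X) {
  if (inherits(model, "pwl_model")) return(predict_proba(model, X))
  if (inherits(model, "baseline_model")) return(predict_proba(model, X))
  abort("Unsupported model type.", class = "pwlscore_validation_error")
}
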