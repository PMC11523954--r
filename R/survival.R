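#' Kaplan-Meier estimate per quartile group
#'
#' Product-limit estimator of the survival function, per group, as a tidy
#' step-function table suitable for any plotting layer.
#'
#' @param time Follow-up times in days (>= 0).
#' @param event Event flags (1 = event, 0 = censored).
#' @param groups Optional group labels (e.g. quartiles Q1-Q4); `NULL`
#'   estimates a single curve.
#' @return Tibble with `group`, `time`, `n_risk`, `n_event`, `survival`;
#'   right-continuous and non-increasing within group, with S(0) = 1.
#' @export
km_estimate <- function(time, event, groups = NULL) {
  check_surv_input(time, event)
  if (is.null(groups)) groups <- rep("all", length(time))
  if (any(table(groups) < 1)) {
    abort("Every group needs at least one sample.",
          class = "pwlscore_invalid_parameter")
  }
  sf <- survival::survfit(
    survival::Surv(time, event) ~ g,
    data = data.frame(time = time, event = event, g = groups))
  strata <- if (is.null(sf$strata)) {
    rep(unique(as.character(groups)), length(sf$time))
  } else {
    rep(sub("^g=", "", names(sf$strata)), sf$strata)
  }
  tibble::tibble(
    group = strata, time = sf$time, n_risk = sf$n.risk,
    n_event = sf$n.event, survival = sf$surv
  )
}

check_surv_input <- function(time, event) {
  if (any(!is.finite(time)) || any(time < 0)) {
    abort("Times must be finite and >= 0.",
          class = "pwlscore_validation_error")
  }
  if (!all(event %in% c(0, 1))) {
    abort("Event flags must be 0/1.", class = "pwlscore_validation_error")
  }
  invisible(NULL)
}

#' k-group log-rank test
#'
#' @param time,event As in [km_estimate()].
#' @param groups Group labels; at least two non-empty groups.
#' @return One-row tibble: `statistic`, `df`, `p_value` (chi-square with
#'   k-1 degrees of freedom under the null).
#' @export
logrank_test <- function(time, event, groups) {
  check_surv_input(time, event)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    abort("Need at least two non-empty groups.",
          class = "pwlscore_invalid_parameter")
  }
  if (sum(event) == 0) {
    abort("Log-rank test undefined with no events.",
          class = "pwlscore_undefined_test")
  }
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ g,
    data = data.frame(time = time, event = event, g = droplevels(groups)))
  df <- length(sd$n) - 1
  tibble::tibble(
    statistic = sd$chisq, df = df,
    p_value = pchisq(sd$chisq, df, lower.tail = FALSE)
  )
}

#' Harrell's concordance index
#'
#' C = (concordant + tied-score/2) / comparable pairs, over pairs
#' comparable under Harrell's rules: the member with the earlier time must
#' have had the event; pairs with tied times are comparable only when
#' exactly one member has the event (the censored member counts as
#' surviving longer). A pair is concordant when the higher risk score
#' belongs to the member with the shorter time.
#'
#' Scores oriented as "higher = better prognosis" (e.g. simple prediction
#' scores, where the top quartile has the best survival) should be passed
#' with `higher_risk = FALSE`, which flips their sign.
#'
#' @param time,event As in [km_estimate()].
#' @param risk Per-sample real risk scores.
#' @param higher_risk If `TRUE` (default) higher scores mean higher risk
#'   (shorter expected survival).
#' @return C-index in \[0, 1\].
#' @export
harrell_c <- function(time, event, risk, higher_risk = TRUE) {
  check_surv_input(time, event)
  if (length(risk) != length(time)) {
    abort("`risk` must align with `time`.",
          class = "pwlscore_dimension_error")
  }
  if (!higher_risk) risk <- -risk
  n <- length(time)

  # vectorized enumeration over ordered pairs (i shorter, j longer)
  ti <- rep(time, each = n); tj <- rep(time, times = n)
  ei <- rep(event, each = n); ej <- rep(event, times = n)
  ri <- rep(risk, each = n); rj <- rep(risk, times = n)

  comparable <- (ti < tj & ei == 1) | (ti == tj & ei == 1 & ej == 0)
  if (!any(comparable)) {
    abort("No comparable pairs.", class = "pwlscore_undefined_test")
  }
  conc <- sum(comparable & ri > rj)
  tied <- sum(comparable & ri == rj)
  (conc + tied / 2) / sum(comparable)
}

#' Quartile x response contingency analysis
#'
#' Builds the 4 x 2 table of quartile group against responder status,
#' tests association with the chi-square test (no continuity correction,
#' df = 3), and reports the per-group correct-prediction fractions under
#' the convention that low-score groups are expected to be non-responders
#' and high-score groups responders (Q1 correct = non-responder fraction,
#' Q4 correct = responder fraction). A Q1-vs-Q4 2 x 2 chi-square is
#' reported alongside.
#'
#' @param groups Quartile labels Q1-Q4 (from [quartile_groups()]).
#' @param responder Binary responder labels (0/1), defined for all samples.
#' @return A list of class `quartile_response`: `table` (4 x 2 counts),
#'   `chisq` tibble (statistic, df, p_value, expected-cell warning flag),
#'   `chisq_q1_q4` tibble, and `by_group` tibble with responder and
#'   correct-prediction fractions.
#' @export
quartile_response_table <- function(groups, responder) {
  if (anyNA(responder)) {
    abort("Responder label must be defined for every sample.",
          class = "pwlscore_validation_error")
  }
  groups <- factor(groups, levels = paste0("Q", 1:4))
  responder <- factor(responder, levels = c(0, 1),
                      labels = c("non_responder", "responder"))
  tab <- table(group = groups, response = responder)

  test <- suppressWarnings(chisq.test(tab, correct = FALSE))
  low_expected <- any(test$expected < 1)
  chisq <- tibble::tibble(
    statistic = unname(test$statistic), df = unname(test$parameter),
    p_value = test$p.value, low_expected_cells = low_expected
  )

  tab14 <- tab[c("Q1", "Q4"), ]
  test14 <- suppressWarnings(chisq.test(tab14, correct = FALSE))
  chisq14 <- tibble::tibble(
    statistic = unname(test14$statistic), df = unname(test14$parameter),
    p_value = test14$p.value
  )

  by_group <- tibble::tibble(
    group = rownames(tab),
    n = as.integer(rowSums(tab)),
    responders = as.integer(tab[, "responder"]),
    responder_fraction = as.numeric(tab[, "responder"] / rowSums(tab)),
    expected = c("non_responder", "non_responder", "responder", "responder")
  )
  by_group$correct_fraction <- ifelse(
    by_group$expected == "responder",
    by_group$responder_fraction, 1 - by_group$responder_fraction)

  structure(list(table = tab, chisq = chisq, chisq_q1_q4 = chisq14,
                 by_group = by_group),
            class = "quartile_response")
}

#' @export
print.quartile_response <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-square(%d) = %.3f, p = %.4g\n",
              x$chisq$df, x$chisq$statistic, x$chisq$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.quartile_response <- function(x, ...) x$by_group

#' @exportS3Method generics::glance
glance.quartile_response <- function(x, ...) {
  tibble::tibble(
    statistic = x$chisq$statistic, df = x$chisq$df,
    p_value = x$chisq$p_value,
    statistic_q1_q4 = x$chisq_q1_q4$statistic,
    p_value_q1_q4 = x$chisq_q1_q4$p_value
  )
}
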