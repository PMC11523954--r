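#' Plot Kaplan-Meier curves
#'
#' @param object A tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot step-function plot, one curve per group.
#' @export
plot_km <- function(object, ...) {
  start <- object |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  dat <- dplyr::bind_rows(
    start, object[, c("group", "time", "survival")]) |>
    dplyr::arrange(.data$group, .data$time)
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days", y = "Survival probability",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Plot an importance-score report
#'
#' Bar chart of importance scores with the extraction cutoff marked.
#'
#' @param report Tibble from [importance_scores()] (optionally joined with
#'   median weights).
#' @param cutoff Extraction cutoff to draw (default 0.1).
#' @param top_n Show at most this many features (default 25).
#' @return A ggplot object.
#' @export
plot_importance <- function(report, cutoff = 0.1, top_n = 25) {
  dat <- utils::head(report[order(-report$score), ], top_n)
  dat$feature <- factor(dat$feature, levels = rev(dat$feature))
  ggplot2::ggplot(dat, ggplot2::aes(.data$score, .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = "Importance score (top-decile rate)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.quartile_response <- function(object, ...) {
  dat <- object$by_group
  ggplot2::ggplot(dat, ggplot2::aes(.data$group,
                                    .data$responder_fraction)) +
    ggplot2::geom_col() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Score quartile", y = "Responder fraction") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pwl_model <- function(object, ...) {
  dat <- tibble::tibble(epoch = seq_along(object$history),
                        loss = object$history)
  ggplot2::ggplot(dat, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Training cross-entropy") +
    ggplot2::theme_minimal()
}
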