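#' Call PSA progression on a longitudinal measurement series
#'
#' Applies the biochemical progression rule used for castration-resistance
#' assessment under ADT. A measurement triggers progression iff it
#' simultaneously satisfies all three clauses:
#' \itemize{
#'   \item PSA value >= 2.0 ng/mL;
#'   \item a rise of >= 50% from the running nadir, i.e. the value is at
#'     least 1.5 x the lowest value observed *before* the current
#'     measurement;
#'   \item it is the third of three consecutive strictly increasing
#'     measurements, each pair separated by at least 7 days.
#' }
#' The progression day is the day of the earliest such measurement. The
#' call is monotone: appending later measurements can never un-flag an
#' earlier progression.
#'
#' @param series A data frame with columns `day` (non-decreasing) and `psa`
#'   (non-negative), one row per measurement, or the long output of
#'   [simulate_psa_series()] restricted to one sample.
#' @return A one-row tibble: `progressed` (logical), `progression_day`
#'   (`NA` unless progressed), `trigger` (`"psa"` or `NA`).
#' @examples
#' s <- data.frame(day = c(0, 14, 28, 42), psa = c(1.0, 1.2, 1.5, 2.1))
#' call_psa_progression(s)
#' @export
call_psa_progression <- function(series) {
  if (!all(c("day", "psa") %in% names(series)) || nrow(series) < 1) {
    abort("`series` needs columns `day` and `psa` and at least one row.",
          class = "pwlscore_validation_error")
  }
  day <- series$day
  psa <- series$psa
  if (is.unsorted(day)) {
    abort("`series` must be sorted by day.",
          class = "pwlscore_validation_error")
  }
  if (any(!is.finite(psa)) || any(psa < 0)) {
    abort("PSA values must be finite and non-negative.",
          class = "pwlscore_validation_error")
  }

  n <- length(psa)
  prog_day <- NA_real_
  if (n >= 3) {
    for (i in 3:n) {
      nadir <- min(psa[seq_len(i - 1)])
      three_rises <- psa[i - 2] < psa[i - 1] && psa[i - 1] < psa[i] &&
        (day[i - 1] - day[i - 2]) >= 7 && (day[i] - day[i - 1]) >= 7
      if (psa[i] >= 2.0 && psa[i] >= 1.5 * nadir && three_rises) {
        prog_day <- day[i]
        break
      }
    }
  }
  tibble::tibble(
    progressed = !is.na(prog_day),
    progression_day = prog_day,
    trigger = if (is.na(prog_day)) NA_character_ else "psa"
  )
}

#' Call PSA progression for every sample of a long measurement table
#'
#' @param psa_long Long table with columns `sample_id`, `day`, `psa`.
#' @return A tibble with one row per sample: `sample_id`, `progressed`,
#'   `progression_day`, `trigger`.
#' @export
call_psa_progression_all <- function(psa_long) {
  psa_long |>
    dplyr::arrange(.data$sample_id, .data$day) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(~ call_psa_progression(.x)) |>
    dplyr::ungroup()
}

#' Label responders at a landmark with censoring exclusions
#'
#' Implements the 2-year landmark outcome definition: a patient who
#' progresses to castration resistance on or before the landmark is a
#' non-responder; a patient followed at least to the landmark without
#' progression is a responder; a patient censored before the landmark
#' without progression cannot be classified and is excluded (and counted).
#'
#' @param cohort A data frame with a `sample_id` column and a follow-up
#'   time column (days).
#' @param progression_day Per-sample progression day (`NA` if none), in the
#'   order of `cohort` rows, or a data frame with `sample_id` and
#'   `progression_day` columns (e.g. from [call_psa_progression_all()]).
#' @param followup_col Name of the follow-up time column (default
#'   `"pfs_time"`).
#' @param landmark_days Landmark, default 730 days (2 years).
#' @return The cohort tibble restricted to classifiable samples with a
#'   `responder` column (1 = responder, 0 = non-responder), plus attributes
#'   `excluded` (tibble of excluded samples) and `n_excluded`.
#' @export
label_responders <- function(cohort, progression_day,
                             followup_col = "pfs_time",
                             landmark_days = 730) {
  if (is.data.frame(progression_day)) {
    m <- match(cohort$sample_id, progression_day$sample_id)
    progression_day <- progression_day$progression_day[m]
  }
  if (length(progression_day) != nrow(cohort)) {
    abort("`progression_day` must align with the cohort rows.",
          class = "pwlscore_dimension_error")
  }
  followup <- cohort[[followup_col]]
  if (is.null(followup)) {
    abort(sprintf("Follow-up column `%s` not found.", followup_col),
          class = "pwlscore_schema_error")
  }

  non_resp <- !is.na(progression_day) & progression_day <= landmark_days
  resp <- !non_resp & followup >= landmark_days
  excluded <- !non_resp & !resp

  out <- cohort[!excluded, , drop = FALSE]
  out$responder <- as.integer(resp[!excluded])
  out <- tibble::as_tibble(out)
  attr(out, "excluded") <- tibble::as_tibble(cohort[excluded, , drop = FALSE])
  attr(out, "n_excluded") <- sum(excluded)
  out
}

#' Randomly split a cohort into discovery and validation sets
#'
#' Simple (unstratified) random split at the given ratio. The validation
#' size is `floor(validation_fraction * n)`, so a cohort of 119 patients at
#' 7:3 yields 82 discovery and 37 validation samples.
#'
#' @param cohort Data frame with a `sample_id` column.
#' @param validation_fraction Fraction assigned to validation (default 0.3).
#' @param seed Integer seed; same seed gives the identical assignment.
#' @return A tibble `sample_id`, `cohort` (`"discovery"`/`"validation"`).
#' @examples
#' co <- tibble::tibble(sample_id = sprintf("S%03d", 1:119))
#' table(split_cohort(co, seed = 1)$cohort)
#' @export
split_cohort <- function(cohort, validation_fraction = 0.3, seed = 1L) {
  n <- nrow(cohort)
  if (n < 10) {
    abort("Need at least 10 samples to split.",
          class = "pwlscore_invalid_parameter")
  }
  check_fraction(validation_fraction, "validation_fraction", 0, 1,
                 lo_open = TRUE, hi_open = TRUE)
  seed <- check_seed(seed)
  n_val <- floor(validation_fraction * n)
  withr::with_seed(seed, idx <- sample.int(n, n_val))
  assignment <- rep("discovery", n)
  assignment[idx] <- "validation"
  tibble::tibble(sample_id = cohort$sample_id, cohort = assignment)
}
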