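#' Simulation configuration for synthetic ADT cohorts
#'
#' Bundles and validates every knob of the synthetic-cohort generator:
#' cohort size, numbers of binary and quantitative clinical features, the
#' minor-allele frequencies of the SNP panel, the effect vector of the
#' responder model on the preprocessed (±1 / z) scale, an optional
#' subgroup-heterogeneity specification, missingness and censoring rates,
#' and the survival model parameters.
#'
#' Feature order is fixed: binary clinical features first, then quantitative
#' clinical features, then SNPs. `effect_vector` must have one coefficient
#' per feature in that order.
#'
#' @param n_samples Number of patients (>= 10).
#' @param n_binary_clinical,n_quant_clinical Numbers of binary and
#'   quantitative clinical features.
#' @param snp_mafs Numeric vector of minor-allele frequencies in (0, 0.5];
#'   one SNP per entry. May be empty.
#' @param effect_vector Per-feature coefficients of the responder logistic
#'   model on the preprocessed scale. Defaults to all zeros.
#' @param heterogeneity Optional subgroup specification: a list with
#'   elements `effects` (list of exactly two alternative effect vectors),
#'   and either `by` (name of a binary clinical feature, e.g. `"bin_1"`,
#'   whose ±1 value defines the subgroup — observable heterogeneity) or
#'   `prob` (probability of latent subgroup 1). When set, the subgroup
#'   overrides `effect_vector`.
#' @param intercept Intercept of the responder model (log-odds scale).
#' @param missing_rate Fraction in \[0, 1) of clinical values set missing,
#'   completely at random. Genotypes are never made missing.
#' @param censor_rate Fraction in \[0, 1): each sample is independently
#'   exposed to a uniform censoring time on (0, `censor_horizon`) with this
#'   probability.
#' @param hazard_scale Baseline exponential hazard (events per day) of the
#'   progression endpoint; cancer-specific and overall death use
#'   `hazard_scale / 3` and `hazard_scale / 2`.
#' @param hazard_coef Log-hazard change per unit of the responder linear
#'   predictor; positive values make samples with larger linear predictors
#'   fail sooner.
#' @param censor_horizon Upper end (days) of the uniform censoring window.
#' @param binary_prevalence Bernoulli prevalence of the +1 level of each
#'   binary clinical feature (recycled).
#' @param quant_mean,quant_sd Mean and SD of quantitative clinical features
#'   on their raw scale (recycled).
#' @param seed Master seed; every random draw of the generator flows from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_samples,
                       n_binary_clinical = 0L,
                       n_quant_clinical = 0L,
                       snp_mafs = numeric(),
                       effect_vector = NULL,
                       heterogeneity = NULL,
                       intercept = 0,
                       missing_rate = 0,
                       censor_rate = 0.2,
                       hazard_scale = 1 / 1000,
                       hazard_coef = 0.5,
                       censor_horizon = 1825,
                       binary_prevalence = 0.3,
                       quant_mean = 0,
                       quant_sd = 1,
                       seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 10) {
    abort("`n_samples` must be a single number >= 10.",
          class = "pwlscore_invalid_parameter")
  }
  n_samples <- as.integer(n_samples)
  n_binary_clinical <- as.integer(n_binary_clinical)
  n_quant_clinical <- as.integer(n_quant_clinical)
  if (length(snp_mafs) > 0) {
    if (any(!is.finite(snp_mafs)) || any(snp_mafs <= 0) || any(snp_mafs > 0.5)) {
      abort("All `snp_mafs` must lie in (0, 0.5].",
            class = "pwlscore_invalid_parameter")
    }
  }
  check_fraction(missing_rate, "missing_rate", 0, 1, hi_open = TRUE)
  check_fraction(censor_rate, "censor_rate", 0, 1, hi_open = TRUE)
  if (!is.numeric(hazard_scale) || hazard_scale <= 0) {
    abort("`hazard_scale` must be positive.",
          class = "pwlscore_invalid_parameter")
  }

  d <- n_binary_clinical + n_quant_clinical + length(snp_mafs)
  if (is.null(effect_vector)) effect_vector <- numeric(d)
  if (length(effect_vector) != d) {
    abort(sprintf(
      "`effect_vector` has length %d but the config defines %d features.",
      length(effect_vector), d), class = "pwlscore_dimension_error")
  }

  feature_names <- c(
    if (n_binary_clinical > 0) paste0("bin_", seq_len(n_binary_clinical)),
    if (n_quant_clinical > 0) paste0("quant_", seq_len(n_quant_clinical)),
    if (length(snp_mafs) > 0) paste0("snp_", seq_along(snp_mafs))
  )

  if (!is.null(heterogeneity)) {
    if (!is.list(heterogeneity) || is.null(heterogeneity$effects) ||
        length(heterogeneity$effects) != 2L) {
      abort("`heterogeneity` must be a list with two `effects` vectors.",
            class = "pwlscore_invalid_parameter")
    }
    lens <- lengths(heterogeneity$effects)
    if (any(lens != d)) {
      abort("Each heterogeneity effect vector must match the feature count.",
            class = "pwlscore_dimension_error")
    }
    if (!is.null(heterogeneity$by)) {
      if (!heterogeneity$by %in% feature_names[seq_len(n_binary_clinical)]) {
        abort("`heterogeneity$by` must name a binary clinical feature.",
              class = "pwlscore_invalid_parameter")
      }
    } else if (is.null(heterogeneity$prob)) {
      heterogeneity$prob <- 0.5
    }
  }

  structure(list(
    n_samples = n_samples,
    n_binary_clinical = n_binary_clinical,
    n_quant_clinical = n_quant_clinical,
    snp_mafs = as.numeric(snp_mafs),
    effect_vector = as.numeric(effect_vector),
    heterogeneity = heterogeneity,
    intercept = intercept,
    missing_rate = missing_rate,
    censor_rate = censor_rate,
    hazard_scale = hazard_scale,
    hazard_coef = hazard_coef,
    censor_horizon = censor_horizon,
    binary_prevalence = rep_len(binary_prevalence, max(1L, n_binary_clinical)),
    quant_mean = rep_len(quant_mean, max(1L, n_quant_clinical)),
    quant_sd = rep_len(quant_sd, max(1L, n_quant_clinical)),
    feature_names = feature_names,
    seed = check_seed(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> n =", x$n_samples,
      "| features:", x$n_binary_clinical, "binary +",
      x$n_quant_clinical, "quantitative +",
      length(x$snp_mafs), "SNPs\n")
  cat("  missing_rate =", x$missing_rate,
      "censor_rate =", x$censor_rate,
      "seed =", x$seed, "\n")
  invisible(x)
}
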