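#' Simulate SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Draws minor-allele counts independently per SNP and per sample with the
#' Hardy-Weinberg genotype probabilities \eqn{((1-p)^2, 2p(1-p), p^2)} for
#' counts (0, 1, 2), where \eqn{p} is the minor-allele frequency.
#'
#' @param mafs Vector of minor-allele frequencies, each in (0, 0.5].
#' @param n Number of samples.
#' @param seed Integer seed; the draw is reproducible and leaves the global
#'   RNG state untouched.
#'
#' @return Integer matrix (`n` rows, one column per SNP, named `snp_i`).
#' @examples
#' g <- simulate_genotypes(c(0.1, 0.4), n = 100, seed = 1)
#' colMeans(g) # approx 2 * mafs
#' @export
simulate_genotypes <- function(mafs, n, seed = 1L) {
  if (length(mafs) == 0) {
    abort("`mafs` must contain at least one frequency.",
          class = "pwlscore_invalid_parameter")
  }
  if (any(!is.finite(mafs)) || any(mafs <= 0) || any(mafs > 0.5)) {
    abort("All minor-allele frequencies must lie in (0, 0.5].",
          class = "pwlscore_invalid_parameter")
  }
  seed <- check_seed(seed)
  n <- as.integer(n)
  withr::with_seed(seed, {
    g <- vapply(mafs, function(p) rbinom(n, size = 2L, prob = p), integer(n))
  })
  g <- matrix(as.integer(g), nrow = n)
  colnames(g) <- paste0("snp_", seq_along(mafs))
  g
}

# linear predictor of the responder model on the preprocessed scale
sim_linpred <- function(Z, config, subgroup) {
  if (is.null(config$heterogeneity)) {
    drop(Z %*% config$effect_vector) + config$intercept
  } else {
    eff <- config$heterogeneity$effects
    eta <- numeric(nrow(Z))
    for (g in 1:2) {
      idx <- subgroup == g
      if (any(idx)) eta[idx] <- drop(Z[idx, , drop = FALSE] %*% eff[[g]])
    }
    eta + config$intercept
  }
}

#' Simulate a synthetic clinical + genotype cohort
#'
#' Generates a cohort with the statistical structure assumed by the
#' downstream modelling pipeline: binary clinical features coded ±1,
#' Gaussian quantitative features, Hardy-Weinberg SNP genotypes, a binary
#' responder label drawn from a logistic model on the preprocessed feature
#' scale (optionally with subgroup-specific effect vectors), and three
#' exponential proportional-hazards survival endpoints (PFS, CSS, OS) whose
#' log-hazard is `hazard_coef` times the same linear predictor. Uniform
#' censoring is applied at the configured rate, and missingness is injected
#' completely at random into clinical features only.
#'
#' The linear predictor uses the *preprocessed* feature values: ±1 for
#' binary features, `(x - mean) / sd` for quantitative features (true
#' generative parameters), and `(count - 2p) / sqrt(2p(1-p))` for SNPs.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `sample_id`, all features, `subgroup`
#'   (when heterogeneity is configured), `responder` (1 = no progression to
#'   castration resistance within the landmark), and `pfs_time`,
#'   `pfs_event`, `css_time`, `css_event`, `os_time`, `os_event` in days.
#'   The true per-sample linear predictor is attached as attribute
#'   `linpred`, and the config as attribute `config`.
#' @examples
#' cfg <- sim_config(n_samples = 50, n_quant_clinical = 3,
#'                   effect_vector = c(1, 0, 0), seed = 7)
#' sim <- simulate_cohort(cfg)
#' mean(sim$responder)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  nb <- config$n_binary_clinical
  nq <- config$n_quant_clinical
  ns <- length(config$snp_mafs)

  withr::with_seed(config$seed, {
    ## raw features and their preprocessed (model-scale) counterparts
    Zb <- Xb <- matrix(numeric(0), n, 0)
    if (nb > 0) {
      Xb <- vapply(seq_len(nb), function(j) {
        ifelse(rbinom(n, 1L, config$binary_prevalence[j]) == 1L, 1, -1)
      }, numeric(n))
      Zb <- Xb # binary features are already on the ±1 scale
    }
    Zq <- Xq <- matrix(numeric(0), n, 0)
    if (nq > 0) {
      Zq <- matrix(rnorm(n * nq), n, nq)
      Xq <- sweep(sweep(Zq, 2, config$quant_sd, `*`), 2, config$quant_mean, `+`)
    }
    Zs <- Xs <- matrix(numeric(0), n, 0)
    if (ns > 0) {
      Xs <- vapply(config$snp_mafs, function(p) rbinom(n, 2L, p), numeric(n))
      Zs <- sweep(Xs, 2, 2 * config$snp_mafs, `-`)
      Zs <- sweep(Zs, 2, sqrt(2 * config$snp_mafs * (1 - config$snp_mafs)), `/`)
    }
    X <- cbind(Xb, Xq, Xs)
    Z <- cbind(Zb, Zq, Zs)
    colnames(X) <- colnames(Z) <- config$feature_names

    ## subgroup assignment (observed feature or latent indicator)
    subgroup <- NULL
    if (!is.null(config$heterogeneity)) {
      if (!is.null(config$heterogeneity$by)) {
        subgroup <- ifelse(X[, config$heterogeneity$by] > 0, 1L, 2L)
      } else {
        subgroup <- ifelse(
          runif(n) < config$heterogeneity$prob, 1L, 2L)
      }
    }

    eta <- sim_linpred(Z, config, subgroup)
    responder <- rbinom(n, 1L, plogis(eta))

    ## survival endpoints: exponential PH, shared linear predictor
    rate_mult <- exp(config$hazard_coef * eta)
    endpoints <- list(
      pfs = rexp(n, config$hazard_scale * rate_mult),
      css = rexp(n, config$hazard_scale / 3 * rate_mult),
      os  = rexp(n, config$hazard_scale / 2 * rate_mult)
    )
    censored_unit <- runif(n) < config$censor_rate
    ctime <- ifelse(censored_unit, runif(n, 0, config$censor_horizon), Inf)
    surv <- lapply(endpoints, function(tt) {
      list(time = pmin(tt, ctime), event = as.integer(tt <= ctime))
    })

    ## MCAR missingness on clinical features only
    if (config$missing_rate > 0 && (nb + nq) > 0) {
      clin <- seq_len(nb + nq)
      mask <- matrix(runif(n * length(clin)) < config$missing_rate,
                     n, length(clin))
      X[, clin][mask] <- NA_real_
    }
  })

  out <- tibble::as_tibble(as.data.frame(X))
  out <- tibble::add_column(out,
    sample_id = sprintf("S%04d", seq_len(n)), .before = 1)
  if (!is.null(subgroup)) out$subgroup <- subgroup
  out$responder <- responder
  for (ep in names(surv)) {
    out[[paste0(ep, "_time")]] <- surv[[ep]]$time
    out[[paste0(ep, "_event")]] <- surv[[ep]]$event
  }
  attr(out, "linpred") <- eta
  attr(out, "config") <- config
  out
}

#' Simulate longitudinal PSA series with a controlled progression fraction
#'
#' Constructs per-sample PSA measurement series (day, ng/mL) such that an
#' exact, pre-specified fraction of series satisfies the full PSA
#' progression definition — a value of at least 2.0 ng/mL, at least 50%
#' above the running nadir, and the third of three consecutive rises each
#' at least one week apart — while every other series violates at least one
#' clause by construction. The flagged count is `round(progression_fraction
#' * n)`: a construction, not a sampling outcome.
#'
#' Non-progressing series cycle through three failure modes: monotone
#' decline (no rises), rises that stay below 2.0 ng/mL, and rises above
#' 2.0 ng/mL that never reach 50% above the nadir.
#'
#' @param n Number of patients.
#' @param progression_fraction Fraction in \[0, 1\] of series that progress.
#' @param seed Integer seed (controls magnitudes, not clause outcomes).
#' @return A long tibble (`sample_id`, `day`, `psa`), with the true
#'   progression flag per sample attached as attribute `truth`.
#' @export
simulate_psa_series <- function(n, progression_fraction, seed = 1L) {
  check_fraction(progression_fraction, "progression_fraction")
  seed <- check_seed(seed)
  n <- as.integer(n)
  n_prog <- round(progression_fraction * n)

  days_base <- c(0, 28, 56, 84)
  days_rise <- c(98, 112, 126)

  withr::with_seed(seed, {
    series <- lapply(seq_len(n), function(i) {
      b <- runif(1, 5, 50)
      if (i <= n_prog) {
        m <- b * runif(1, 0.05, 0.3)
        vals <- c(b, b * 0.7, b * 0.45, m, m * 1.15, m * 1.35,
                  max(2.0, m * 1.55))
      } else {
        mode <- (i - n_prog) %% 3L
        if (mode == 0L) {
          # monotone decline: no increases at all
          vals <- b * c(1, 0.8, 0.6, 0.45, 0.35, 0.28, 0.22)
        } else if (mode == 1L) {
          # rises, but every value stays below 2.0 ng/mL
          m <- 0.5
          vals <- c(1.9, 1.2, 0.8, m, m * 1.6, m * 2.5, 1.9)
        } else {
          # high values, three rises, but rise from nadir < 50%
          m <- runif(1, 3, 8)
          vals <- c(m * 1.33, m * 1.1, m * 1.05, m,
                    m * 1.1, m * 1.25, m * 1.4)
        }
      }
      tibble::tibble(
        sample_id = sprintf("P%04d", i),
        day = c(days_base, days_rise),
        psa = vals
      )
    })
  })
  out <- dplyr::bind_rows(series)
  attr(out, "truth") <- c(rep(TRUE, n_prog), rep(FALSE, n - n_prog))
  out
}
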