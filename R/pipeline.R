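#' Configuration for a full analysis run
#'
#' Bundles everything [run_full()] needs: the cohort source (a
#' [sim_config()] or an existing labeled cohort tibble), the feature-set
#' definitions, the model list, seeds and tuning grids.
#'
#' @param sim A [sim_config()] used to simulate the cohort, or `NULL` when
#'   `cohort` is supplied.
#' @param cohort Optional pre-built cohort tibble with feature columns, a
#'   `responder` column, and `<endpoint>_time`/`<endpoint>_event` columns.
#' @param feature_sets Named list of character vectors of feature columns.
#'   `NULL` builds the three study-style sets from a simulated cohort:
#'   `clinical`, `small_snps` (clinical + 2 SNPs), `large_snps` (clinical +
#'   all SNPs).
#' @param models Subset of `c("pwl", "elastic_net_lr", "gradient_boosting")`.
#' @param endpoints Survival endpoints to evaluate (prefixes of
#'   `_time`/`_event` columns).
#' @param seed Master seed for split, folds and model fits.
#' @param validation_fraction Validation share of the random split.
#' @param threshold_rule Operating-point rule for sensitivity/specificity.
#' @param importance_cutoff Importance-score cutoff for feature extraction.
#' @param importance_mode Sample-wise importance mode, see
#'   [sample_importance()].
#' @param pwl A base [pwl_config()].
#' @param pwl_grid Hyper-parameter grid for the PWL CV (data frame).
#' @param score_higher_risk Orientation of simple scores when computing
#'   Harrell's C: `TRUE` treats higher scores as higher risk, which matches
#'   the default generator, whose hazard rises with the responder linear
#'   predictor.
#' @param output_dir Optional directory; when set, every intermediate is
#'   written as delimited text / JSON.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = NULL, cohort = NULL, feature_sets = NULL,
                       models = c("pwl", "elastic_net_lr",
                                  "gradient_boosting"),
                       endpoints = c("pfs", "css", "os"),
                       seed = 1L, validation_fraction = 0.3,
                       threshold_rule = "youden",
                       importance_cutoff = 0.1,
                       importance_mode = "weight",
                       pwl = pwl_config(),
                       pwl_grid = expand.grid(
                         weight_decay = c(1e-4, 1e-3, 1e-2),
                         depth = c(2L, 3L)),
                       score_higher_risk = TRUE,
                       output_dir = NULL) {
  if (is.null(sim) && is.null(cohort)) {
    abort("Provide either `sim` or `cohort`.",
          class = "pwlscore_invalid_parameter")
  }
  structure(list(
    sim = sim, cohort = cohort, feature_sets = feature_sets,
    models = match.arg(models, several.ok = TRUE),
    endpoints = endpoints, seed = check_seed(seed),
    validation_fraction = validation_fraction,
    threshold_rule = threshold_rule,
    importance_cutoff = importance_cutoff,
    importance_mode = importance_mode,
    pwl = pwl, pwl_grid = pwl_grid,
    score_higher_risk = score_higher_risk,
    output_dir = output_dir
  ), class = "run_config")
}

#' Default synthetic study profile
#'
#' A ready-made [sim_config()] emulating the shape of an ADT cohort
#' analysis: mixed binary/quantitative clinical features, a 46-SNP panel
#' under Hardy-Weinberg equilibrium, signal on a handful of clinical
#' features and SNPs, mild missingness and censoring.
#'
#' @param n_samples Cohort size (default 500).
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
default_sim_config <- function(n_samples = 500, seed = 1L) {
  n_bin <- 8L
  n_quant <- 12L
  mafs <- rep(c(0.1, 0.2, 0.3, 0.4, 0.25, 0.45, 0.15, 0.35, 0.28, 0.12,
                0.22, 0.38, 0.18, 0.42, 0.32, 0.08, 0.26, 0.48, 0.2, 0.3,
                0.24, 0.36, 0.14), length.out = 46)
  eff <- numeric(n_bin + n_quant + 46)
  names(eff) <- c(paste0("bin_", 1:n_bin), paste0("quant_", 1:n_quant),
                  paste0("snp_", 1:46))
  eff[c("bin_1", "quant_1", "quant_2")] <- c(0.5, 0.8, -0.8)
  eff[c("snp_1", "snp_2")] <- c(1, -1)
  eff[paste0("snp_", 3:8)] <- rep(c(0.6, -0.6), 3)
  sim_config(
    n_samples = n_samples, n_binary_clinical = n_bin,
    n_quant_clinical = n_quant, snp_mafs = mafs,
    effect_vector = unname(eff), intercept = 0,
    missing_rate = 0.03, censor_rate = 0.25, seed = seed
  )
}

# mean fold metrics at a fixed configuration: the discovery-cohort
# reporting convention (fold-mean AUC/sensitivity/specificity)
cv_fold_metrics <- function(fit_fun, X, y, folds, threshold_rule) {
  k <- max(folds)
  m <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- folds != f
    fit <- fit_fun(X[tr, , drop = FALSE], y[tr])
    evaluate_model(fit, X[!tr, , drop = FALSE], y[!tr], threshold_rule)
  })
  dplyr::summarise(m, dplyr::across(c("auc", "sensitivity", "specificity"),
                                    mean))
}

#' Run the full analytic pipeline end-to-end
#'
#' Executes, from a single master seed: cohort simulation (or ingestion),
#' the random discovery/validation split, preprocessing frozen on the
#' discovery cohort, model training with 5-fold CV hyper-parameter
#' selection for every model x feature set, AUC/sensitivity/specificity
#' reporting (discovery = fold means; validation = single discovery
#' refit), the importance-score procedure and simple prediction scores per
#' feature set, pooled quartile groups, the quartile x response
#' contingency test, and per-endpoint log-rank tests and Harrell's
#' C-indices.
#'
#' Everything computed from the discovery cohort (preprocess state, folds,
#' CV selection, sample-wise weights, importance scores, median-weight
#' signs) never touches validation data.
#'
#' @param config A [run_config()].
#' @return A `run_report` list: `cohort`, `split`, `preprocess`,
#'   `metrics` (Table-1-style tibble), per-feature-set `importance`,
#'   `simple_models`, `scores`, `quartiles`, `response_tables`,
#'   `survival` (log-rank + C-index tibble), `km` curves, and `config`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  cohort <- if (!is.null(config$cohort)) config$cohort else
    simulate_cohort(config$sim)

  reserved <- c("sample_id", "subgroup", "responder",
                paste0(rep(config$endpoints, each = 2),
                       c("_time", "_event")))
  all_features <- setdiff(names(cohort), reserved)

  feature_sets <- config$feature_sets
  if (is.null(feature_sets)) {
    snps <- grep("^snp_", all_features, value = TRUE)
    clinical <- setdiff(all_features, snps)
    feature_sets <- list(clinical = clinical)
    if (length(snps) >= 2) {
      feature_sets$small_snps <- c(clinical, snps[1:2])
    }
    if (length(snps) > 2) {
      feature_sets$large_snps <- c(clinical, snps)
    }
  }
  for (fs in names(feature_sets)) {
    missing_cols <- setdiff(feature_sets[[fs]], names(cohort))
    if (length(missing_cols) > 0) {
      abort(sprintf("Feature set `%s` references missing columns: %s",
                    fs, paste(missing_cols, collapse = ", ")),
            class = "pwlscore_config_error")
    }
  }

  split <- split_cohort(cohort, config$validation_fraction, seed)
  is_disc <- split$cohort == "discovery"

  # preprocessing frozen on discovery; SNP columns declared quantitative
  snp_cols <- grep("^snp_", all_features, value = TRUE)
  types <- setNames(rep("quantitative", length(snp_cols)), snp_cols)
  state <- fit_preprocess(cohort[is_disc, all_features, drop = FALSE],
                          types = types)
  Z_all <- apply_preprocess(state, cohort[, all_features, drop = FALSE])
  y <- cohort$responder

  metrics <- list()
  pwl_models <- list()
  cv_records <- list()

  for (fs in names(feature_sets)) {
    cols <- feature_sets[[fs]]
    Zd <- as.matrix(Z_all[is_disc, cols, drop = FALSE])
    Zv <- as.matrix(Z_all[!is_disc, cols, drop = FALSE])
    yd <- y[is_disc]
    yv <- y[!is_disc]

    for (mdl in config$models) {
      if (mdl == "pwl") {
        cv <- select_hyperparams_cv(Zd, yd, grid = config$pwl_grid,
                                    seed = seed, config = config$pwl)
        best_cfg <- config$pwl
        for (nm in names(config$pwl_grid)) {
          best_cfg[[nm]] <- cv$grid[[nm]][cv$best]
        }
        best_cfg$seed <- seed
        fit <- fit_pwl(Zd, yd, best_cfg)
        disc <- cv_fold_metrics(function(Xt, yt) fit_pwl(Xt, yt, best_cfg),
                                Zd, yd, cv$folds, config$threshold_rule)
        cv_records[[paste(fs, mdl, sep = ".")]] <- cv
        pwl_models[[fs]] <- fit
      } else {
        kind <- mdl
        fit <- fit_baseline(kind, Zd, yd, k = 5L, seed = seed)
        best_row <- fit$cv$grid[fit$cv$best, , drop = FALSE]
        disc <- cv_fold_metrics(
          function(Xt, yt) {
            structure(list(kind = kind,
                           fit = baseline_engine(kind, Xt, yt, best_row,
                                                 seed),
                           d = ncol(Xt)),
                      class = "baseline_model")
          }, Zd, yd, fit$cv$folds, config$threshold_rule)
        cv_records[[paste(fs, mdl, sep = ".")]] <- fit$cv
      }
      val <- evaluate_model(fit, Zv, yv, config$threshold_rule)
      metrics[[paste(fs, mdl, sep = ".")]] <- dplyr::bind_rows(
        dplyr::mutate(disc, cohort = "discovery"),
        dplyr::mutate(val[, c("auc", "sensitivity", "specificity")],
                      cohort = "validation")
      ) |>
        dplyr::mutate(feature_set = fs, model = mdl, .before = 1)
    }
  }
  metrics <- dplyr::bind_rows(metrics)

  # importance -> simple scores -> quartiles -> survival, per feature set
  importance <- list()
  simple_models <- list()
  scores <- list()
  quartiles <- list()
  response_tables <- list()
  surv_rows <- list()
  km <- list()

  for (fs in names(pwl_models)) {
    cols <- feature_sets[[fs]]
    Zd <- as.matrix(Z_all[is_disc, cols, drop = FALSE])
    sw <- extract_weights(pwl_models[[fs]], Zd)
    imp <- sample_importance(sw, X = Zd, mode = config$importance_mode)
    rep_fs <- importance_scores(imp)
    med <- tidy(pwl_models[[fs]], Zd)
    importance[[fs]] <- dplyr::left_join(rep_fs, med, by = "feature")

    sm <- tryCatch(
      extract_features(rep_fs, med, cutoff = config$importance_cutoff),
      error = function(e) NULL)
    simple_models[[fs]] <- sm
    if (is.null(sm)) next

    sc <- simple_score(sm, Z_all[, cols, drop = FALSE])
    scores[[fs]] <- sc
    qg <- quartile_groups(sc)
    quartiles[[fs]] <- qg
    response_tables[[fs]] <- quartile_response_table(qg$group, y)

    for (ep in config$endpoints) {
      tt <- cohort[[paste0(ep, "_time")]]
      ev <- cohort[[paste0(ep, "_event")]]
      if (is.null(tt)) next
      lr <- logrank_test(tt, ev, qg$group)
      cc <- harrell_c(tt, ev, sc,
                      higher_risk = config$score_higher_risk)
      surv_rows[[paste(fs, ep, sep = ".")]] <- tibble::tibble(
        feature_set = fs, endpoint = ep,
        logrank_statistic = lr$statistic, logrank_df = lr$df,
        logrank_p = lr$p_value, c_index = cc
      )
      km[[paste(fs, ep, sep = ".")]] <- km_estimate(tt, ev, qg$group)
    }
  }

  report <- structure(list(
    cohort = cohort, split = split, preprocess = state,
    feature_sets = feature_sets, cv = cv_records,
    pwl_models = pwl_models, metrics = metrics,
    importance = importance, simple_models = simple_models,
    scores = scores, quartiles = quartiles,
    response_tables = response_tables,
    survival = dplyr::bind_rows(surv_rows), km = km,
    config = config
  ), class = "run_report")

  if (!is.null(config$output_dir)) write_run_report(report)
  report
}

# persist every intermediate as delimited text / JSON
write_run_report <- function(report) {
  dir <- report$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(report$cohort, file.path(dir, "cohort.tsv"))
  readr::write_tsv(report$split, file.path(dir, "split.tsv"),
                   progress = FALSE)
  write_preprocess_state(report$preprocess,
                         file.path(dir, "preprocess_state.json"))
  readr::write_tsv(report$metrics, file.path(dir, "metrics.tsv"),
                   progress = FALSE)
  for (fs in names(report$importance)) {
    readr::write_tsv(report$importance[[fs]],
                     file.path(dir, paste0("importance_", fs, ".tsv")),
                     progress = FALSE)
    if (!is.null(report$simple_models[[fs]])) {
      readr::write_tsv(tidy(report$simple_models[[fs]]),
                       file.path(dir, paste0("simple_model_", fs, ".tsv")),
                       progress = FALSE)
    }
  }
  if (nrow(report$survival %||% tibble::tibble()) > 0) {
    readr::write_tsv(report$survival, file.path(dir, "survival.tsv"),
                     progress = FALSE)
  }
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", nrow(x$cohort), "samples;",
      length(x$feature_sets), "feature sets x",
      length(unique(x$metrics$model)), "models\n")
  print(x$metrics, n = Inf)
  invisible(x)
}

#' Rank models per feature set by validation AUC
#'
#' Deterministic ranking of the fitted models within each feature set by
#' validation AUC, ties broken by the discovery (fold-mean) AUC.
#'
#' @param report A `run_report` from [run_full()].
#' @return Tibble `feature_set`, `model`, `validation_auc`,
#'   `discovery_auc`, `rank`.
#' @export
compare_models <- function(report) {
  stopifnot(inherits(report, "run_report"))
  wide <- report$metrics |>
    dplyr::select("feature_set", "model", "cohort", "auc") |>
    tidyr::pivot_wider(names_from = "cohort", values_from = "auc")
  wide |>
    dplyr::group_by(.data$feature_set) |>
    dplyr::arrange(dplyr::desc(.data$validation),
                   dplyr::desc(.data$discovery), .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::rename(validation_auc = "validation",
                  discovery_auc = "discovery")
}
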