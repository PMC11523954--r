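test_that("genotype generator rejects out-of-range frequencies", {
  expect_error(simulate_genotypes(0, 10), class = "pwlscore_invalid_parameter")
  expect_error(simulate_genotypes(0.6, 10),
               class = "pwlscore_invalid_parameter")
  expect_error(simulate_genotypes(numeric(), 10),
               class = "pwlscore_invalid_parameter")
})

test_that("genotypes follow Hardy-Weinberg closed-form frequencies", {
  n <- 1e5
  g <- simulate_genotypes(c(0.25, 0.5), n, seed = 11)
  expect_true(all(g %in% 0:2))

  # maf = 0.5: mean count 1.0 within 3 binomial standard errors
  se <- sqrt(2 * 0.5 * 0.5 / n)
  expect_lt(abs(mean(g[, 2]) - 1.0), 3 * se)

  # maf = 0.25: genotype frequencies (0.5625, 0.375, 0.0625)
  obs <- tabulate(g[, 1] + 1L, 3)
  expected <- c(0.75^2, 2 * 0.25 * 0.75, 0.25^2)
  gof <- chisq.test(obs, p = expected)
  expect_gt(gof$p.value, 0.001)
})

test_that("same seed reproduces the identical cohort bit for bit", {
  cfg <- sim_config(n_samples = 60, n_binary_clinical = 2,
                    n_quant_clinical = 3, snp_mafs = c(0.2, 0.4),
                    effect_vector = c(0.5, 0, 1, 0, -1, 0.3, 0),
                    missing_rate = 0.1, seed = 42)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  g1 <- simulate_genotypes(c(0.3), 50, seed = 5)
  g2 <- simulate_genotypes(c(0.3), 50, seed = 5)
  expect_identical(g1, g2)
})

test_that("null effects give responder rate at the intercept and no feature association", {
  cfg <- sim_config(n_samples = 4000, n_quant_clinical = 4,
                    intercept = 0.8, seed = 3)
  sim <- simulate_cohort(cfg)
  p0 <- plogis(0.8)
  se <- sqrt(p0 * (1 - p0) / 4000)
  expect_lt(abs(mean(sim$responder) - p0), 3 * se)

  # responder independent of every feature under the null
  cors <- vapply(paste0("quant_", 1:4), function(f) {
    abs(cor(sim[[f]], sim$responder))
  }, numeric(1))
  expect_lt(max(cors), 0.06)
})

test_that("a strong single-feature effect is recoverable by its marginal AUC", {
  cfg <- sim_config(n_samples = 2000, n_quant_clinical = 3,
                    effect_vector = c(3, 0, 0), seed = 9)
  sim <- simulate_cohort(cfg)
  expect_gt(auc(sim$quant_1, sim$responder), 0.85)
})

test_that("latent opposite-sign subgroups null out the pooled signal", {
  d <- 3
  het <- list(prob = 0.5, effects = list(c(3, 0, 0), c(-3, 0, 0)))
  cfg <- sim_config(n_samples = 2000, n_quant_clinical = d,
                    heterogeneity = het, seed = 21)
  sim <- simulate_cohort(cfg)
  pooled <- auc(sim$quant_1, sim$responder)
  expect_lt(abs(pooled - 0.5), 0.05)
  for (g in 1:2) {
    sub <- sim[sim$subgroup == g, ]
    a <- auc(sub$quant_1, sub$responder)
    expect_gt(max(a, 1 - a), 0.8) # strong within-subgroup signal
  }
})

test_that("larger linear predictors give stochastically shorter event times", {
  cfg <- sim_config(n_samples = 2000, n_quant_clinical = 2,
                    effect_vector = c(1.5, -1), censor_rate = 0, seed = 13)
  sim <- simulate_cohort(cfg)
  eta <- attr(sim, "linpred")
  expect_true(all(sim$pfs_event == 1))
  expect_lt(cor(eta, sim$pfs_time, method = "spearman"), 0)
})

test_that("missingness hits clinical features only and genotypes stay in 0..2", {
  cfg <- sim_config(n_samples = 300, n_binary_clinical = 3,
                    n_quant_clinical = 3, snp_mafs = c(0.2, 0.3),
                    missing_rate = 0.2, seed = 8)
  sim <- simulate_cohort(cfg)
  clin <- unlist(sim[paste0(c("bin_", "bin_", "bin_", "quant_", "quant_",
                              "quant_"), c(1:3, 1:3))])
  expect_gt(sum(is.na(clin)), 0)
  snps <- unlist(sim[c("snp_1", "snp_2")])
  expect_false(anyNA(snps))
  expect_true(all(snps %in% 0:2))
  expect_true(all(sim$responder %in% 0:1))
  expect_true(all(sim$pfs_time >= 0 & sim$os_time >= 0))
})

test_that("effect vector length mismatches are rejected", {
  expect_error(
    sim_config(n_samples = 20, n_quant_clinical = 3,
               effect_vector = c(1, 2)),
    class = "pwlscore_dimension_error")
})

test_that("PSA series generator hits the requested progression fraction exactly", {
  s0 <- simulate_psa_series(30, 0, seed = 2)
  calls0 <- call_psa_progression_all(s0)
  expect_false(any(calls0$progressed))

  s1 <- simulate_psa_series(30, 1, seed = 2)
  calls1 <- call_psa_progression_all(s1)
  expect_true(all(calls1$progressed))

  s <- simulate_psa_series(200, 0.4, seed = 7)
  calls <- call_psa_progression_all(s)
  expect_identical(sum(calls$progressed), 80L)
  truth <- attr(s, "truth")
  expect_identical(calls$progressed[order(calls$sample_id)], truth)
})
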