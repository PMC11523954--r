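# numerical check of the hand-written backpropagation
test_that("analytic gradients match numerical differentiation", {
  withr::with_seed(2, {
    n <- 7; d <- 3
    X <- matrix(rnorm(n * d), n, d)
    y <- rbinom(n, 1, 0.5)
  })
  params <- withr::with_seed(1, pwlscore:::pwl_init_params(d = 3, depth = 2,
                                                           width = 5))
  wd <- 1e-3; lw <- 0.01
  g <- pwlscore:::pwl_grad(params, X, y, weight_decay = wd, lambda_w = lw)

  loss_at <- function(p) {
    fwd <- pwlscore:::pwl_forward(p, X)
    pwlscore:::pwl_loss_value(fwd$p, y) + pwlscore:::pwl_penalty(p, wd) +
      lw * mean(rowSums(fwd$w^2))
  }
  eps <- 1e-6
  for (nm in pwlscore:::pwl_param_names(params)) {
    P <- pwlscore:::pwl_get(params, nm)
    idx <- seq_len(min(length(P), 20L)) # spot-check up to 20 entries
    for (i in idx) {
      Pp <- P; Pp[i] <- Pp[i] + eps
      Pm <- P; Pm[i] <- Pm[i] - eps
      num <- (loss_at(pwlscore:::pwl_set(params, nm, Pp)) -
                loss_at(pwlscore:::pwl_set(params, nm, Pm))) / (2 * eps)
      expect_lt(abs(num - pwlscore:::pwl_get(g$grads, nm)[i]), 1e-6)
    }
  }
})

test_that("training fits separable data and the loss decreases", {
  dat <- separable_data(n = 500, d = 5, seed = 3)
  fit <- fit_pwl(dat$X, dat$y, fast_pwl(seed = 3))
  expect_gte(auc(predict_proba(fit, dat$X), dat$y), 0.99)
  expect_lte(fit$history[length(fit$history)], fit$history[1])
})

test_that("predictions are consistent with the emitted weight vectors", {
  dat <- logistic_data(300, beta = c(1, -1, 0.5), seed = 4)
  fit <- fit_pwl(dat$X, dat$y, fast_pwl(seed = 4))
  p <- predict_proba(fit, dat$X)
  sw <- extract_weights(fit, dat$X)
  p_manual <- plogis(rowSums(sw$weights * dat$X) + sw$intercept)
  expect_lt(max(abs(p - p_manual)), 1e-6)
  expect_true(all(p > 0 & p < 1))
})

test_that("the generator is a pure function of the input row", {
  dat <- logistic_data(120, beta = c(1, -0.5), seed = 6)
  fit <- fit_pwl(dat$X, dat$y, fast_pwl(seed = 6))

  # duplicate rows get identical probabilities
  Xdup <- rbind(dat$X[1, ], dat$X[1, ])
  expect_equal(predict_proba(fit, Xdup)[1], predict_proba(fit, Xdup)[2])

  # permuting samples permutes outputs identically
  perm <- sample(nrow(dat$X))
  expect_equal(predict_proba(fit, dat$X)[perm],
               predict_proba(fit, dat$X[perm, ]))

  # an all-zero row predicts sigma(b): weights multiply zeros
  z <- matrix(0, 1, 2)
  swz <- extract_weights(fit, z)
  expect_equal(predict_proba(fit, z), plogis(swz$intercept))
})

test_that("a zeroed generator head emits p = 0.5 everywhere", {
  params <- withr::with_seed(1, pwlscore:::pwl_init_params(3, 2, 8))
  params$Wo[] <- 0
  params$bo[] <- 0
  fwd <- pwlscore:::pwl_forward(params, matrix(rnorm(15), 5, 3))
  expect_equal(fwd$p, rep(0.5, 5))
})

test_that("fitting is deterministic given seed, config and data", {
  dat <- logistic_data(150, beta = c(1.5, 0), seed = 7)
  f1 <- fit_pwl(dat$X, dat$y, fast_pwl(seed = 7))
  f2 <- fit_pwl(dat$X, dat$y, fast_pwl(seed = 7))
  expect_identical(f1$params, f2$params)
  expect_identical(predict_proba(f1, dat$X), predict_proba(f2, dat$X))
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_pwl(X, rep(1, 20), fast_pwl()),
               class = "pwlscore_degenerate_labels")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_pwl(Xna, rep_len(0:1, 20), fast_pwl()),
               class = "pwlscore_validation_error")
  fit <- fit_pwl(X, rep_len(0:1, 20), fast_pwl())
  expect_error(predict_proba(fit, matrix(0, 2, 3)),
               class = "pwlscore_dimension_error")
})

test_that("stratified folds are balanced: n = 82 gives 17/17/16/16/16", {
  y <- rep_len(0:1, 82)
  folds <- make_stratified_folds(y, k = 5, seed = 1)
  expect_equal(sort(as.integer(table(folds)), decreasing = TRUE),
               c(17, 17, 16, 16, 16))
  # class balance: each fold within one of the per-class quota
  for (f in 1:5) {
    expect_lte(abs(mean(y[folds == f]) - mean(y)), 0.1)
  }
})

test_that("cross-validation selects sensible grid points", {
  dat <- logistic_data(200, beta = c(2, -2, 0), seed = 8)

  # a one-point grid is selected trivially
  cv1 <- select_hyperparams_cv(dat$X, dat$y,
                               grid = data.frame(weight_decay = 1e-3),
                               seed = 8, config = fast_pwl(seed = 8))
  expect_equal(cv1$best, 1L)
  expect_equal(length(cv1$grid$fold_aucs[[1]]), 5)

  # a zero-learning-rate point stays at chance and loses
  cv2 <- select_hyperparams_cv(
    dat$X, dat$y,
    grid = data.frame(learning_rate = c(0, 1e-3)),
    seed = 8, config = fast_pwl(seed = 8))
  expect_equal(cv2$best, 2L)

  expect_error(
    select_hyperparams_cv(dat$X[1:3, ], dat$y[1:3],
                          grid = data.frame(weight_decay = 1e-3), k = 5),
    class = "pwlscore_invalid_parameter")
})

test_that("null-label cross-validated AUC sits at chance level", {
  withr::with_seed(9, {
    X <- matrix(rnorm(500 * 5), 500, 5)
    y <- rbinom(500, 1, 0.5)
  })
  cv <- select_hyperparams_cv(X, y, grid = data.frame(weight_decay = 1e-3),
                              seed = 9, config = fast_pwl(seed = 9))
  expect_gte(cv$grid$mean_auc[1], 0.35)
  expect_lte(cv$grid$mean_auc[1], 0.65)
})

test_that("per-sample weights recover homogeneous global coefficients", {
  beta <- c(2, -2, 1.5, -1.5, 1, -1, 0.5, -0.5, 0, 0)
  dat <- logistic_data(1500, beta = beta, seed = 10)
  fit <- fit_pwl(dat$X, dat$y, pwl_config(epochs = 300, seed = 10))
  med <- tidy(fit, dat$X)$median_weight
  expect_gte(cor(med, beta, method = "spearman"), 0.8)
})

test_that("a fitted model survives a JSON checkpoint round trip", {
  dat <- logistic_data(100, beta = c(1, -1), seed = 12)
  fit <- fit_pwl(dat$X, dat$y, fast_pwl(seed = 12))
  path <- withr::local_tempfile(fileext = ".json")
  write_pwl_model(fit, path)
  fit2 <- read_pwl_model(path)
  expect_equal(predict_proba(fit2, dat$X), predict_proba(fit, dat$X),
               tolerance = 1e-12)
})
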