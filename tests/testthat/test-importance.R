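test_that("sample-wise importance is the absolute weight", {
  W <- rbind(c(3, -5, 1), c(0, 0, 0))
  imp <- sample_importance(W)
  expect_equal(imp[1, ], c(3, 5, 1))
  expect_equal(imp[2, ], c(0, 0, 0))
  # |.| symmetry: flipping every weight leaves importances unchanged
  expect_equal(sample_importance(-W), imp)
})

test_that("the weight-times-value mode multiplies by the feature values", {
  W <- rbind(c(2, -1))
  X <- rbind(c(0.5, 3))
  expect_equal(sample_importance(W, X, mode = "weight_x"),
               rbind(c(1, 3)))
  expect_error(sample_importance(W, mode = "weight_x"),
               class = "pwlscore_invalid_parameter")
})

test_that("top-decile ranking counts k = ceiling(0.1 d) features per sample", {
  # d = 60 -> k = 6
  withr::with_seed(20, M60 <- matrix(runif(10 * 60), 10, 60))
  r60 <- importance_scores(M60)
  expect_equal(attr(r60, "k"), 6L)

  # a feature dominating every sample scores 1.0
  M <- matrix(runif(50 * 20), 50, 20)
  M[, 7] <- 10
  colnames(M) <- paste0("f", 1:20)
  r <- importance_scores(M)
  expect_equal(r$score[r$feature == "f7"], 1.0)

  # d = 5, identical strict ordering: exactly one feature (k = 1) scores 1
  M5 <- matrix(rep(c(5, 4, 3, 2, 1), each = 8), 8, 5)
  r5 <- importance_scores(M5)
  expect_equal(attr(r5, "k"), 1L)
  expect_equal(sort(r5$score, decreasing = TRUE), c(1, 0, 0, 0, 0))
})

test_that("ranking conserves mass: scores sum to k, exactly k ranked per sample", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      n <- sample(3:40, 1)
      d <- sample(2:30, 1)
      M <- matrix(runif(n * d), n, d)
      r <- importance_scores(M)
      k <- attr(r, "k")
      expect_equal(sum(r$score) * n, n * k)
    }
  })
})

test_that("feature extraction applies the strict cutoff and median-weight signs", {
  report <- tibble::tibble(feature = c("psa", "hypertension", "noise"),
                           score = c(0.107, 0.776, 0.099))
  med <- c(psa = -0.009, hypertension = 0.012, noise = 0.5)
  model <- extract_features(report, med)
  expect_setequal(model$feature, c("psa", "hypertension")) # 0.099 dropped
  expect_equal(model$sign[model$feature == "hypertension"], 1)
  expect_equal(model$sign[model$feature == "psa"], -1)

  # monotone in the cutoff: raising it never adds features
  for (cut in c(0.2, 0.5, 0.8)) {
    larger <- tryCatch(extract_features(report, med, cutoff = cut)$feature,
                       error = function(e) character())
    expect_true(all(larger %in% model$feature))
  }

  # zero-median features are dropped with a warning; empty model errors
  expect_warning(
    m2 <- extract_features(tibble::tibble(feature = c("a", "b"),
                                          score = c(0.5, 0.4)),
                           c(a = 0, b = 1)),
    regexp = "zero median")
  expect_equal(m2$feature, "b")
  expect_error(
    suppressWarnings(extract_features(
      tibble::tibble(feature = "a", score = 0.5), c(a = 0))),
    class = "pwlscore_empty_model")
})

test_that("simple scores are signed sums of preprocessed values", {
  report <- tibble::tibble(feature = c("u", "v"), score = c(0.9, 0.8))
  model <- extract_features(report, c(u = 0.4, v = -0.2))

  # single feature, sigma = +1: identity
  one <- extract_features(tibble::tibble(feature = "u", score = 0.9),
                          c(u = 0.4))
  expect_equal(simple_score(one, data.frame(u = c(-1, 0, 2))), c(-1, 0, 2))

  # opposite signs on equal values cancel
  expect_equal(simple_score(model, data.frame(u = 3, v = 3)), 0)

  # brute-force spreadsheet oracle on a 5 x 3 matrix
  withr::with_seed(22, X <- matrix(rnorm(15), 5, 3,
                                   dimnames = list(NULL, c("u", "v", "w"))))
  m3 <- extract_features(
    tibble::tibble(feature = c("u", "v", "w"), score = c(1, 1, 1)),
    c(u = 2, v = -3, w = 0.5))
  expected <- apply(X, 1, function(r) r["u"] - r["v"] + r["w"])
  expect_equal(simple_score(m3, as.data.frame(X)), unname(expected),
               tolerance = 1e-12)

  expect_error(simple_score(model, data.frame(u = 1)),
               class = "pwlscore_schema_error")
})

test_that("quartile groups are contiguous, balanced and tie-stable", {
  q <- quartile_groups(1:8)
  expect_equal(as.character(q$group),
               rep(paste0("Q", 1:4), each = 2))

  q112 <- quartile_groups(rnorm(112))
  expect_equal(unname(table(q112$group)), rep(28L, 4),
               ignore_attr = TRUE)

  tied <- quartile_groups(rep(1, 12))
  expect_equal(unname(table(tied$group)), rep(3L, 4), ignore_attr = TRUE)
  expect_identical(tied$group, quartile_groups(rep(1, 12))$group)

  expect_error(quartile_groups(1:3), class = "pwlscore_invalid_parameter")
  b <- attr(q, "boundaries")
  expect_equal(b$min, c(1, 3, 5, 7))
  expect_equal(b$max, c(2, 4, 6, 8))
})
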