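# shared fixtures, built in code

# quick PWL configuration for module tests (acceptance tests use defaults)
fast_pwl <- function(seed = 1L, ...) {
  pwl_config(depth = 2L, width = 16L, epochs = 120L, patience = 30L,
             seed = seed, ...)
}

# linearly separable two-class data with a clear margin
separable_data <- function(n = 500, d = 5, seed = 1L) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * d), n, d)
    y <- as.integer(X[, 1] > 0)
    X[, 1] <- X[, 1] + ifelse(y == 1, 1, -1) # widen the margin
  })
  list(X = X, y = y)
}

# homogeneous logistic cohort on the preprocessed scale
logistic_data <- function(n, beta, intercept = 0, seed = 1L) {
  d <- length(beta)
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * d), n, d)
    y <- rbinom(n, 1, plogis(intercept + drop(X %*% beta)))
  })
  list(X = X, y = y)
}

# brute-force AUC by pair counting (independent oracle)
auc_bruteforce <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# brute-force Harrell C by exhaustive comparable-pair enumeration
harrell_bruteforce <- function(time, event, risk) {
  n <- length(time)
  conc <- tied <- comp <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- (time[i] < time[j] && event[i] == 1) ||
        (time[i] == time[j] && event[i] == 1 && event[j] == 0)
      if (!comparable) next
      comp <- comp + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) tied <- tied + 1
    }
  }
  (conc + tied / 2) / comp
}
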