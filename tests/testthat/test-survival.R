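test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # no events: survival stays at 1
  km0 <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km0$survival == 1))

  # events at days 2 and 4 among 4 subjects, no earlier censoring
  km <- km_estimate(c(2, 4, 6, 8), c(1, 1, 0, 0))
  expect_equal(km$survival[km$time == 2], 0.75)
  expect_equal(km$survival[km$time == 4], 0.5)

  # moving a censoring time that falls after the last event changes nothing
  km2 <- km_estimate(c(2, 4, 6, 9), c(1, 1, 0, 0))
  expect_equal(km2$survival[km2$time == 4], 0.5)
  expect_true(all(diff(km$survival) <= 0))
})

test_that("Kaplan-Meier equals the empirical survival function without censoring", {
  withr::with_seed(23, tt <- sample(1:50, 30, replace = TRUE))
  km <- km_estimate(tt, rep(1, 30))
  emp <- vapply(km$time, function(t) mean(tt > t), numeric(1))
  expect_equal(km$survival, emp)
})

test_that("log-rank statistic matches the hand calculation and null behavior", {
  # duplicated groups: no difference to detect
  t0 <- c(3, 6, 9, 3, 6, 9)
  e0 <- c(1, 1, 0, 1, 1, 0)
  g0 <- rep(c("A", "B"), each = 3)
  r0 <- logrank_test(t0, e0, g0)
  expect_lt(r0$statistic, 1e-10)
  expect_gt(r0$p_value, 0.999)

  # six-sample table worked through the observed-minus-expected arithmetic:
  # O_A = 2, E_A = 26/15, V = 433/450 -> chi-square = 32/433
  r <- logrank_test(c(1, 3, 5, 2, 4, 6), c(1, 1, 0, 1, 1, 1),
                    rep(c("A", "B"), each = 3))
  expect_equal(r$statistic, 32 / 433, tolerance = 1e-6)
  expect_equal(r$df, 1)

  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")),
               class = "pwlscore_undefined_test")
  expect_error(logrank_test(c(1, 2), c(1, 1), c("A", "A")),
               class = "pwlscore_invalid_parameter")
})

test_that("four-group log-rank has df = 3", {
  withr::with_seed(24, {
    tt <- rexp(80, 1 / 100)
    gg <- rep(paste0("Q", 1:4), each = 20)
  })
  r <- logrank_test(tt, rep(1, 80), gg)
  expect_equal(r$df, 3)
})

test_that("Harrell's C handles ties, orientation and boundary orderings", {
  # all scores equal: everything ties, C = 0.5
  expect_equal(harrell_c(c(1, 2, 3), c(1, 1, 1), c(5, 5, 5)), 0.5)

  # perfect anti-ordering of times by risk: C = 1
  expect_equal(harrell_c(c(3, 2, 1), c(1, 1, 1), c(1, 2, 3)), 1.0)

  # monotone transform invariance
  withr::with_seed(25, {
    tt <- rexp(40, 1 / 50)
    ev <- rbinom(40, 1, 0.7)
    rk <- rnorm(40)
  })
  expect_equal(harrell_c(tt, ev, rk), harrell_c(tt, ev, exp(rk)))

  # "higher score = better prognosis" orientation flips the sign
  expect_equal(harrell_c(tt, ev, rk, higher_risk = FALSE),
               harrell_c(tt, ev, -rk))

  expect_error(harrell_c(c(1, 2), c(0, 0), c(1, 2)),
               class = "pwlscore_undefined_test")
})

test_that("Harrell's C equals exhaustive pair enumeration and survival::concordance", {
  withr::with_seed(26, {
    for (rep in 1:10) {
      n <- sample(5:20, 1)
      tt <- sample(1:10, n, replace = TRUE) # tied times on purpose
      ev <- rbinom(n, 1, 0.7)
      if (sum(ev) == 0) ev[1] <- 1
      rk <- sample(seq(0, 2, 0.5), n, replace = TRUE) # tied scores too
      expect_equal(harrell_c(tt, ev, rk), harrell_bruteforce(tt, ev, rk))
      cfit <- survival::concordance(survival::Surv(tt, ev) ~ rk,
                                    reverse = TRUE)
      expect_equal(harrell_c(tt, ev, rk), unname(cfit$concordance))
    }
  })
})

test_that("quartile-response tables recover printed-style fractions", {
  # 27 per quartile; 21 non-responders correct in Q1, 16 responders in Q4
  groups <- rep(paste0("Q", 1:4), each = 27)
  responder <- c(rep(c(0, 1), c(21, 6)), rep(c(0, 1), c(14, 13)),
                 rep(c(0, 1), c(12, 15)), rep(c(0, 1), c(11, 16)))
  qr <- quartile_response_table(groups, responder)
  by <- qr$by_group
  expect_equal(by$correct_fraction[by$group == "Q1"], 21 / 27,
               tolerance = 1e-12)
  expect_equal(by$correct_fraction[by$group == "Q4"], 16 / 27,
               tolerance = 1e-12)
  expect_equal(qr$chisq$df, 3)
  expect_lt(qr$chisq$p_value, 0.05)

  # identical response distributions: statistic ~ 0
  flat <- quartile_response_table(rep(paste0("Q", 1:4), each = 10),
                                  rep(rep(c(0, 1), each = 5), 4))
  expect_lt(flat$chisq$statistic, 1e-10)

  # 2x2 collapse matches the textbook chi-square formula
  tab <- qr$table[c("Q1", "Q4"), ]
  n <- sum(tab)
  expected_stat <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
  expect_equal(qr$chisq_q1_q4$statistic, unname(expected_stat))
})

test_that("log-rank is symmetric under label exchange on exchangeable data", {
  withr::with_seed(27, {
    tt <- rexp(60, 1 / 100)
    ev <- rbinom(60, 1, 0.8)
    stats <- replicate(200, {
      logrank_test(tt, ev, sample(rep(c("A", "B"), 30)))$statistic
    })
  })
  expect_lt(abs(mean(stats) - 1), 0.25) # mean of chi-square(1) is 1
})
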