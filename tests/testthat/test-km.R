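test_that("KM matches the hand-computed product-limit estimate", {
  s <- data.frame(time = c(2, 4, 6), event = c(1, 0, 1))
  k <- km_estimate(s)
  ## S = 2/3 on [2, 6), 0 at 6; median at 6
  expect_equal(k$surv[k$time == 2], 2 / 3)
  expect_equal(k$surv[k$time == 6], 0)
  expect_equal(k$median, 6)
  expect_true(all(diff(k$surv) <= 0))
  expect_true(all(diff(k$n_risk) <= 0))
})

test_that("all-censored samples give S = 1, undefined median, RMST = tau", {
  s <- data.frame(time = c(5, 9, 13), event = 0)
  k <- km_estimate(s, tau = 10)
  expect_true(all(k$surv == 1))
  expect_true(is.na(k$median))
  expect_equal(unname(k$rmst[["value"]]), 10)
})

test_that("KM on uncensored data equals the empirical survival function", {
  set.seed(7)
  s <- data.frame(time = rexp(200, 0.1), event = 1)
  k <- km_estimate(s)
  emp <- vapply(k$time, function(t) mean(s$time > t), 0)
  expect_equal(k$surv, emp, tolerance = 1e-12)
})

test_that("RMST approaches the closed-form exponential integral", {
  set.seed(97)
  s <- data.frame(time = rexp(5000, 0.1), event = 1)
  k <- km_estimate(s, tau = 20)
  target <- (1 - exp(-2)) / 0.1
  expect_lt(abs(k$rmst[["value"]] - target) / target, 0.02)
})

test_that("two-sample tests match a risk-set-by-risk-set oracle", {
  ## worked set: A has events at 1 and 3; B an event at 2, censored at 4
  a <- data.frame(time = c(1, 3), event = 1)
  b <- data.frame(time = c(2, 4), event = c(1, 0))
  time <- c(a$time, b$time); event <- c(a$event, b$event)
  group <- c(1, 1, 0, 0)
  for (m in c("logrank", "peto")) {
    got <- two_sample_test(a, b, m)
    want <- brute_force_two_sample(time, event, group,
                                   if (m == "logrank") "unit" else "peto")
    expect_equal(got$statistic, want, tolerance = 1e-10, info = m)
  }
  ## richer random pattern
  set.seed(3)
  a2 <- data.frame(time = rexp(25, 0.1), event = rbinom(25, 1, 0.8))
  b2 <- data.frame(time = rexp(30, 0.15), event = rbinom(30, 1, 0.8))
  t2 <- c(a2$time, b2$time); e2 <- c(a2$event, b2$event)
  g2 <- rep(1:0, c(25, 30))
  for (m in c("logrank", "peto"))
    expect_equal(two_sample_test(a2, b2, m)$statistic,
                 brute_force_two_sample(t2, e2, g2,
                                        if (m == "logrank") "unit" else
                                          "peto"),
                 tolerance = 1e-8, info = m)
})

test_that("identical event patterns across arms give statistic 0, p = 1", {
  a <- data.frame(time = c(2, 5, 9, 12), event = c(1, 1, 0, 1))
  r <- two_sample_test(a, a, "logrank")
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  ## zero events in both groups combined
  z <- data.frame(time = c(3, 6), event = 0)
  rz <- two_sample_test(z, z, "peto")
  expect_equal(c(rz$statistic, rz$p_value), c(0, 1))
})

test_that("log-rank is invariant to monotone time transformations", {
  set.seed(13)
  a <- data.frame(time = rexp(40, 0.1), event = rbinom(40, 1, 0.7))
  b <- data.frame(time = rexp(40, 0.2), event = rbinom(40, 1, 0.7))
  s1 <- two_sample_test(a, b)$statistic
  a2 <- transform(a, time = log1p(time)); b2 <- transform(b, time = log1p(time))
  s2 <- two_sample_test(a2, b2)$statistic
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("Peto-Peto weights (pooled left-continuous KM) never increase", {
  set.seed(17)
  time <- rexp(60, 0.1); event <- rbinom(60, 1, 0.8)
  ut <- sort(unique(time[event == 1]))
  w <- vapply(ut, function(t) {
    s <- 1
    for (tt in ut[ut < t])
      s <- s * (1 - sum(time == tt & event == 1) / sum(time >= tt))
    s
  }, 0)
  expect_true(all(diff(w) <= 0))
})
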