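test_that("log-likelihood matches closed forms and censored-only structure", {
  ## exponential, single observation t = 2, d = 1, rate 0.5
  expect_equal(ps_loglik(2, 1, "exponential", log(0.5)), log(0.5) - 1)
  ## all-censored: only survivor terms remain
  t <- c(3, 7, 11)
  expect_equal(ps_loglik(t, 0, "weibull", 2.5, 1.3),
               sum(log(ps_surv(t, "weibull", 2.5, 1.3))))
  ## event terms add the log hazard
  expect_equal(ps_loglik(t, 1, "weibull", 2.5, 1.3),
               sum(log(ps_surv(t, "weibull", 2.5, 1.3))) +
                 sum(log(ps_haz(t, "weibull", 2.5, 1.3))))
  expect_error(ps_loglik(c(0, 2), 1, "weibull", 2.5, 1.3), "positive")
})

test_that("intercept-only exponential MLE equals events over exposure", {
  set.seed(11)
  d <- data.frame(time = rexp(300, 0.08), event = rbinom(300, 1, 0.8))
  f <- psfit(survival::Surv(time, event) ~ 1, d, family = "exponential")
  expect_equal(unname(exp(coef(f))), sum(d$event) / sum(d$time),
               tolerance = 1e-6)
})

test_that("location and shape coefficients are recovered within 3 SE", {
  set.seed(21)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  truth <- c(3.0, 0.5, 0.2, -0.3)
  tt <- ps_rtime(runif(n), "weibull", truth[1] + truth[2] * x,
                 exp(truth[3] + truth[4] * x))
  cens <- runif(n, 10, 120)
  d <- data.frame(time = pmin(tt, cens), event = as.integer(tt <= cens),
                  x = x)
  f <- psfit(survival::Surv(time, event) ~ x, d, shape = ~x,
             family = "weibull")
  expect_true(f$converged)
  se <- sqrt(diag(vcov(f)))
  expect_true(all(abs(coef(f) - truth) < 3 * se))
})

test_that("fitting agrees with an independent implementation", {
  set.seed(31)
  n <- 600
  x <- rnorm(n)
  tt <- ps_rtime(runif(n), "llogis", 2.8 + 0.3 * x, exp(0.5))
  cens <- runif(n, 5, 120)
  d <- data.frame(time = pmin(tt, cens), event = as.integer(tt <= cens),
                  x = x)
  f <- psfit(survival::Surv(time, event) ~ x, d, family = "llogis")
  fs <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ x, data = d,
                              dist = "llogis")
  expect_equal(f$loglik, as.numeric(logLik(fs)), tolerance = 1e-6)
  expect_equal(unname(coef(f)[["(Intercept)"]]),
               unname(coef(fs)[["scale"]]), tolerance = 1e-4)
  expect_equal(unname(coef(f)[["x"]]), unname(coef(fs)[["x"]]),
               tolerance = 1e-4)
})

test_that("fits are deterministic and AIC/BIC identities hold", {
  set.seed(41)
  d <- data.frame(time = rweibull(200, 1.2, 25), event = 1)
  f1 <- psfit(survival::Surv(time, event) ~ 1, d, family = "gompertz")
  f2 <- psfit(survival::Surv(time, event) ~ 1, d, family = "gompertz")
  expect_identical(coef(f1), coef(f2))
  expect_equal(f1$aic, -2 * f1$loglik + 2 * f1$k)
  expect_equal(f1$bic, -2 * f1$loglik + f1$k * log(f1$n))
  expect_equal(AIC(f1), f1$aic)
  expect_equal(BIC(f1), f1$bic)
})

test_that("model comparison ranks by AIC and refuses mixed datasets", {
  expect_equal(-2 * (-100) + 2 * 3, 206)  # AIC formula on the worked pair
  set.seed(51)
  d <- data.frame(time = rlnorm(300, 2.5, 0.6), event = 1)
  fits <- lapply(c("weibull", "lnorm", "llogis"), function(fam)
    psfit(survival::Surv(time, event) ~ 1, d, family = fam))
  cmp <- compare_models(fits)
  expect_equal(cmp$family[1], "lnorm")
  expect_true(all(diff(cmp$aic) >= 0))
  expect_equal(cmp$delta_aic[1], 0)
  d2 <- d; d2$time <- d2$time + 1
  f_other <- psfit(survival::Surv(time, event) ~ 1, d2, family = "weibull")
  expect_error(compare_models(fits[[1]], f_other), "same samples")
})

test_that("predicted curves honour the lead-in and population averaging", {
  set.seed(61)
  n <- 400
  x <- rbinom(n, 1, 0.4)
  tt <- 4 + ps_rtime(runif(n), "weibull", 2.5 + 0.4 * x, 1.3)
  d <- data.frame(time = tt, event = 1, x = x)
  f <- psfit(survival::Surv(time, event) ~ x, d, family = "weibull",
             lead_in = 4)
  ## flat at 1 before the lead-in ends
  p <- predict(f, data.frame(x = 0), times = c(0, 1, 2, 3, 3.9, 4.5, 10))
  expect_true(all(p$S1[p$time < 4] == 1))
  expect_lt(p$S1[p$time == 10], 1)
  ## horizon 0: the single point S = 1
  p0 <- predict(f, data.frame(x = 0), times = 0)
  expect_equal(p0$S1, 1)
  ## one-row average equals the single-profile curve
  pa <- predict(f, data.frame(x = 1), times = 0:20, average = TRUE)
  ps <- predict(f, data.frame(x = 1), times = 0:20)
  expect_equal(pa$value, ps$S1)
  ## population average equals the brute-force mean of per-row curves
  tab <- data.frame(x = c(0, 0, 1, 1, 1))
  pavg <- predict(f, tab, times = 0:30, average = TRUE)
  per <- sapply(seq_len(nrow(tab)), function(i)
    predict(f, tab[i, , drop = FALSE], times = 0:30)$S1)
  expect_equal(pavg$value, rowMeans(per), tolerance = 1e-12)
  ## missing covariate refused
  expect_error(predict(f, data.frame(z = 1), times = 0:5))
})

test_that("simulated event times reproduce the fitted distribution", {
  set.seed(71)
  d <- data.frame(time = rweibull(500, 1.4, 30), event = 1)
  f <- psfit(survival::Surv(time, event) ~ 1, d, family = "weibull")
  sim <- simulate(f, nsim = 4000, seed = 3)
  expect_equal(dim(sim), c(1, 4000))
  ks <- suppressWarnings(stats::ks.test(sim[1, ], d$time))
  expect_gt(ks$p.value, 0.01)
  ## reproducible given seed
  expect_identical(sim, simulate(f, nsim = 4000, seed = 3))
})

test_that("Cox-Snell residuals of a well-specified fit look unit exponential", {
  set.seed(81)
  d <- data.frame(time = rweibull(800, 1.3, 22), event = 1)
  f <- psfit(survival::Surv(time, event) ~ 1, d, family = "weibull")
  r <- residuals(f)
  expect_equal(mean(r), 1, tolerance = 0.1)
})
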