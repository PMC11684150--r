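exp_tm <- function(lam_rem = 0.1, lam_rel = 0.1, lead_in = 0,
                   relapse = TRUE) {
  transition_model(
    to_remission = list(family = "exponential", mu = log(lam_rem)),
    to_relapse = if (relapse) list(family = "exponential",
                                   mu = log(lam_rel)) else NULL,
    arm = "test", lead_in_weeks = lead_in)
}

test_that("occupancy starts empty and partitions to unity", {
  tr <- simulate_cohort(exp_tm(), n_sim = 2000, horizon_months = 12,
                        seed = 1)
  expect_equal(tr$trace$prop_remission[tr$trace$month == 0], 0)
  expect_equal(tr$trace$prop_remission + tr$trace$prop_csf,
               rep(1, nrow(tr$trace)))
  expect_true(all(tr$trace$prop_remission >= 0 &
                    tr$trace$prop_remission <= 1))
})

test_that("microsimulation matches the two-state Markov closed form", {
  tr <- simulate_cohort(exp_tm(0.1, 0.1), n_sim = 50000,
                        horizon_months = 48, seed = 5)
  wk <- tr$trace$month * 52 / 12
  closed <- 0.5 * (1 - exp(-0.2 * wk))
  dev <- abs(tr$trace$prop_remission - closed)
  expect_true(all(dev[-1] < 3 * tr$trace$se[-1]))
})

test_that("renewal solver reproduces closed forms within O(grid_step)", {
  rn <- solve_renewal(exp_tm(0.1, 0.1), horizon_months = 48,
                      grid_step = 0.25)
  wk <- rn$trace$month * 52 / 12
  closed <- 0.5 * (1 - exp(-0.2 * wk))
  expect_lt(max(abs(rn$trace$prop_remission - closed)), 0.25 * 0.05)
  ## degenerate relapse (never) collapses to 1 - S_remission
  rn2 <- solve_renewal(exp_tm(0.1, relapse = FALSE), horizon_months = 24)
  wk2 <- rn2$trace$month * 52 / 12
  expect_lt(max(abs(rn2$trace$prop_remission - (1 - exp(-0.1 * wk2)))),
            0.25 * 0.05)
})

test_that("absorbing remission equals one minus the remission survivor", {
  tr <- simulate_cohort(exp_tm(0.1, relapse = FALSE), n_sim = 30000,
                        horizon_months = 24, seed = 7)
  wk <- tr$trace$month * 52 / 12
  target <- 1 - exp(-0.1 * wk)
  dev <- abs(tr$trace$prop_remission - target)
  expect_true(all(dev[-1] < 3.5 * tr$trace$se[-1] + 1e-6))
})

test_that("the lead-in delays the first remission entry only", {
  tm4 <- exp_tm(0.2, 0.0001, lead_in = 4)
  tr <- simulate_cohort(tm4, n_sim = 20000, horizon_months = 6, seed = 9)
  wk <- tr$trace$month * 52 / 12
  before <- wk < 4
  expect_true(all(tr$trace$prop_remission[before] == 0))
  rn <- solve_renewal(tm4, horizon_months = 6, grid_step = 0.25)
  expect_true(all(rn$trace$prop_remission[before] == 0))
  expect_gt(tr$trace$prop_remission[wk > 8][1], 0.1)
})

test_that("uniformly faster remission never lowers occupancy", {
  set.seed(11)
  for (rep in 1:3) {
    lam <- runif(1, 0.03, 0.15)
    tr_slow <- solve_renewal(exp_tm(lam, 0.05), horizon_months = 36)
    tr_fast <- solve_renewal(exp_tm(lam * 1.8, 0.05), horizon_months = 36)
    expect_true(all(tr_fast$trace$prop_remission -
                      tr_slow$trace$prop_remission > -1e-6))
  }
})

test_that("fitted covariate-adjusted models drive both engines consistently", {
  set.seed(13)
  n <- 600
  x <- rbinom(n, 1, 0.5)
  t_rem <- ps_rtime(runif(n), "weibull", 2.5 - 0.4 * x, 1.3)
  t_rel <- ps_rtime(runif(n), "weibull", 3.2 + 0.3 * x, 1.1)
  d_rem <- data.frame(time = t_rem, event = 1, x = x)
  d_rel <- data.frame(time = t_rel, event = 1, x = x)
  f_rem <- psfit(survival::Surv(time, event) ~ x, d_rem, family = "weibull")
  f_rel <- psfit(survival::Surv(time, event) ~ x, d_rel, family = "weibull")
  tm <- transition_model(f_rem, f_rel,
                         covariate_table = data.frame(x = c(0, 1)),
                         arm = "DVS", lead_in_weeks = 0)
  ms <- simulate_cohort(tm, n_sim = 30000, horizon_months = 24, seed = 15)
  rn <- solve_renewal(tm, horizon_months = 24, grid_step = 0.1)
  dev <- abs(ms$trace$prop_remission - rn$trace$prop_remission)
  expect_true(all(dev[-1] < 3 * ms$trace$se[-1] + 0.003))
})

test_that("Gompertz horizons that overflow the survivor function are refused", {
  tm <- transition_model(
    to_remission = list(family = "gompertz", mu = log(0.01), anc = 5),
    to_relapse = NULL, arm = "x", lead_in_weeks = 0)
  expect_error(simulate_cohort(tm, 100, horizon_months = 480, seed = 1),
               "overflow")
})

test_that("bias adjustment matches reference moments with logged weights", {
  set.seed(17)
  tab <- data.frame(age = rnorm(400, 40, 10), sev = rbinom(400, 1, 0.5))
  ref <- data.frame(age = rnorm(300, 37, 9), sev = rbinom(300, 1, 0.4))
  ## identical tables: unit weights
  w0 <- bias_adjust(tab, tab)
  expect_equal(w0$weights, rep(1, nrow(tab)), tolerance = 1e-6)
  ## weighted means equal the reference means
  wa <- bias_adjust(tab, ref)
  expect_equal(unname(wa$achieved), unname(wa$target), tolerance = 1e-6)
  expect_equal(mean(wa$weights), 1, tolerance = 1e-9)
  ## infeasible target refused with the constraint named
  bad <- data.frame(age = rep(200, 5), sev = 1)
  expect_error(bias_adjust(tab, bad), "infeasible.*age")
})

test_that("reweighted traces agree with explicit resampling", {
  set.seed(19)
  tab <- data.frame(x = rbinom(300, 1, 0.5))
  ref <- data.frame(x = rbinom(300, 1, 0.25))
  wa <- bias_adjust(tab, ref, vars = "x")
  comp_rem <- list(family = "exponential", mu = log(0.08) - 0.5 * tab$x)
  tm_w <- transition_model(comp_rem, NULL, covariate_table = tab,
                           weights = wa$weights, lead_in_weeks = 0)
  ## explicit population with the reference mix of x
  idx <- sample(seq_len(nrow(tab)), 20000, replace = TRUE,
                prob = wa$weights)
  comp2 <- list(family = "exponential", mu = log(0.08) - 0.5 * tab$x[idx])
  tm_r <- transition_model(comp2, NULL,
                           covariate_table = data.frame(i = idx),
                           lead_in_weeks = 0)
  a <- simulate_cohort(tm_w, n_sim = 20000, horizon_months = 12, seed = 3)
  b <- simulate_cohort(tm_r, n_sim = 20000, horizon_months = 12, seed = 4)
  dev <- abs(a$trace$prop_remission - b$trace$prop_remission)
  se <- sqrt(a$trace$se^2 + b$trace$se^2)
  expect_true(all(dev[-1] < 3.5 * se[-1] + 1e-6))
})

test_that("the remission report tabulates arms and refuses bad months", {
  tr1 <- solve_renewal(exp_tm(0.12, 0.05), horizon_months = 48)
  tr2 <- solve_renewal(exp_tm(0.06, 0.08), horizon_months = 48)
  rep <- remission_table(list(DVS = tr1, SOC = tr2))
  expect_equal(rep$month, c(0, 8, 24, 48))
  expect_equal(rep$DVS[1], 0)
  expect_true(all(rep$difference[-1] > 0))
  expect_equal(rep$difference, rep$DVS - rep$SOC)
  expect_error(remission_table(list(DVS = tr1), months = c(0, 96)),
               "beyond the trace horizon")
})
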