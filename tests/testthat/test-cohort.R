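test_that("generation is byte-identical under a fixed seed", {
  cfg <- exp_cohort_config(n = 80, seed = 5, visit_by = 4, followup = 60)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("record counts and arm allocation follow the configuration", {
  co <- generate_cohort(cohort_config(seed = 3))
  expect_equal(nrow(co$baseline), 212 + 386)
  expect_equal(sum(co$baseline$study == "TRIAL"), 212)
  expect_equal(sum(co$baseline$arm == "DVS" & co$baseline$study == "RWE"), 0)
})

test_that("invalid configurations are refused with the field named", {
  expect_error(cohort_config(n_trial = 0), "n_trial")
  expect_error(cohort_config(lead_in_weeks = -1), "lead_in_weeks")
  expect_error(cohort_config(missingness = list(cdai = c(trial = 1.2,
                                                         rwe = 0))),
               "missingness")
  tm <- default_true_models()
  names(tm)[1] <- "nonsense_outcome"
  expect_error(cohort_config(true_models = tm), "true_models")
})

test_that("covariate sample moments match the configuration", {
  cfg <- cohort_config(n_trial = 10000, n_rwe = 10000,
                       n_unassessed_trial = 1, n_unassessed_rwe = 1,
                       n_trial_dvs = 5000, missingness = list(), seed = 13,
                       visit_schedule = list(
                         trial_weeks = c(0, 4), rwe_gap_meanlog = log(8),
                         rwe_gap_sdlog = 0.5,
                         followup_weeks = c(trial = 4, rwe = 4)))
  co <- generate_cohort(cfg)
  bl <- co$baseline
  tr <- bl[bl$study == "TRIAL", ]; rw <- bl[bl$study == "RWE", ]
  ## ages are floored at 18: closed-form moments of max(X, a), X ~ N(mu, s)
  a <- 18; mu <- 38.2; s <- 13.2
  al <- (a - mu) / s
  m1 <- a * pnorm(al) + mu * (1 - pnorm(al)) + s * dnorm(al)
  m2 <- a^2 * pnorm(al) + (mu^2 + s^2) * (1 - pnorm(al)) +
    dnorm(al) * s * (mu + a)
  expect_equal(mean(tr$age), m1, tolerance = 0.01)
  expect_equal(sd(tr$age), sqrt(m2 - m1^2), tolerance = 0.02)
  expect_equal(mean(rw$gender == "male"), 0.52, tolerance = 0.02)
  expect_equal(mean(tr$prior_bio), 0.795, tolerance = 0.02)
  expect_equal(mean(rw$luminal == "moderate"), 0.36, tolerance = 0.02)
})

test_that("derived remission times recover the configured exponential law", {
  ## exact-observation oracle: latent times straight from the true model
  cfg <- exp_cohort_config(n = 5000, lambda_rem = 0.05, seed = 17,
                           observation = "exact")
  co <- generate_cohort(cfg)
  s <- derive_remission(co, "clinical")
  s <- s[s$study == "TRIAL", ]
  k <- km_estimate(s)
  expect_lt(abs(k$median - log(2) / 0.05) / (log(2) / 0.05), 0.05)
  ## KS distance between empirical times and the true law is small
  ks <- suppressWarnings(
    stats::ks.test(s$time[s$event == 1], function(q) 1 - exp(-0.05 * q)))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("visit observation detects events within one visit gap", {
  cfg <- exp_cohort_config(n = 800, lambda_rem = 0.05, seed = 19,
                           visit_by = 1, keep_latent = TRUE)
  co <- generate_cohort(cfg)
  s <- derive_remission(co, "clinical")
  m <- merge(s[s$event == 1 & s$study == "TRIAL", ],
             co$baseline[, c("patient_id", "latent_clin_rem",
                             "latent_clin_rel")])
  lag <- m$time - m$latent_clin_rem
  expect_true(all(lag >= 0))
  ## closure spells longer than the visit gap are caught within one gap;
  ## shorter spells can only be seen in a later cycle
  long <- (m$latent_clin_rel - m$latent_clin_rem) > 2
  expect_true(all(lag[long] <= 1 + 1e-9))
})

test_that("relapse clocks reset at CPC remission entry by construction", {
  cfg <- exp_cohort_config(n = 300, seed = 23, keep_latent = TRUE)
  co <- generate_cohort(cfg)
  bl <- co$baseline
  expect_true(all(bl$latent_cpc_rem >= bl$latent_clin_rem))
  expect_true(all(bl$latent_cpc_rel >= bl$latent_cpc_rem))
  expect_true(all(bl$latent_clin_rel >= bl$latent_cpc_rel))
})

test_that("missingness injection hits boundary cases and target rates", {
  cfg <- exp_cohort_config(n = 400, seed = 29, visit_by = 4,
                           followup = 100)
  co <- generate_cohort(cfg)
  ## probability 0: identity
  expect_identical(inject_missingness(co, list(pdai_pain = c(trial = 0,
                                                             rwe = 0)),
                                      seed = 1), co)
  ## probability 1: every post-index value missing
  c1 <- inject_missingness(co, list(pdai_pain = c(trial = 1, rwe = 1)),
                           seed = 1)
  expect_true(all(is.na(c1$visits$pdai_pain[c1$visits$week > 0])))
  ## unknown variable refused
  expect_error(inject_missingness(co, list(bogus = c(trial = .1, rwe = .1))),
               "unknown variable")
  ## empirical fraction near the target (within 3 binomial SEs)
  p <- 0.735
  c2 <- inject_missingness(co, list(pdai_pain = c(trial = p, rwe = p)),
                           seed = 2)
  idx <- c2$visits$week > 0
  fr <- mean(is.na(c2$visits$pdai_pain[idx]))
  se <- sqrt(p * (1 - p) / sum(idx))
  expect_lt(abs(fr - p), 3 * se)
  ## MAR mode: missingness gradient follows age
  c3 <- inject_missingness(co, list(cdai = c(trial = 0.5, rwe = 0.5)),
                           seed = 3, mechanism = "mar", mar_coef = 1.5)
  old <- co$baseline$age > median(co$baseline$age)
  expect_gt(mean(is.na(c3$baseline$cdai[old])),
            mean(is.na(c3$baseline$cdai[!old])))
})

test_that("cohorts round-trip through CSV", {
  cfg <- exp_cohort_config(n = 40, seed = 31, visit_by = 8, followup = 48)
  co <- generate_cohort(cfg)
  d <- file.path(tempdir(), "cohort_roundtrip")
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(back$baseline$patient_id, co$baseline$patient_id)
  expect_equal(nrow(back$visits), nrow(co$visits))
  expect_equal(back$visits$week, co$visits$week)
  expect_true(file.exists(file.path(d, "cohort_config.json")))
  unlink(d, recursive = TRUE)
})
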