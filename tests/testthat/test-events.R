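test_that("remission definitions differ exactly by the PDAI clause", {
  ## closure with both PDAI elements 0: both definitions fire at week 8
  v1 <- visit_rows("P1", c(0, 8), c(FALSE, TRUE), c(2, 0), c(2, 0))
  co1 <- mini_cohort(v1)
  clin <- derive_remission(co1, "clinical")
  cpc <- derive_remission(co1, "cpc")
  expect_equal(c(clin$time, clin$event), c(8, 1))
  expect_equal(c(cpc$time, cpc$event), c(8, 1))
  ## closure with pain 1: clinical fires, CPC keeps the patient at risk
  v2 <- visit_rows("P1", c(0, 8, 16), c(FALSE, TRUE, TRUE),
                   c(2, 1, 0), c(2, 0, 0))
  co2 <- mini_cohort(v2)
  clin2 <- derive_remission(co2, "clinical")
  cpc2 <- derive_remission(co2, "cpc")
  expect_equal(c(clin2$time, clin2$event), c(8, 1))
  expect_equal(c(cpc2$time, cpc2$event), c(16, 1))
})

test_that("patients without a qualifying event are censored at observation end", {
  ## no closure ever, proctectomy at week 30
  v <- visit_rows("P1", c(0, 8, 20), FALSE, 2, 2)
  co <- mini_cohort(v, censor_week = 30, censor_reason = "proctectomy")
  s <- derive_remission(co, "clinical")
  expect_equal(c(s$time, s$event), c(30, 0))
  ## a missing closure assessment never qualifies
  v2 <- visit_rows("P1", c(0, 8), c(FALSE, NA), c(2, 0), c(2, 0))
  s2 <- derive_remission(mini_cohort(v2), "clinical")
  expect_equal(s2$event, 0)
})

test_that("relapse clocks start at the first observed CPC remission", {
  ## CPC remission week 12; week 20 pain 1 with closure maintained:
  ## CPC relapse at t = 8, clinical relapse still at risk
  v <- visit_rows("P1", c(0, 12, 20, 28), c(FALSE, TRUE, TRUE, FALSE),
                  c(2, 0, 1, 1), c(2, 0, 0, 0))
  co <- mini_cohort(v)
  cpc <- derive_relapse(co, "cpc")
  clin <- derive_relapse(co, "clinical")
  expect_equal(c(cpc$time, cpc$event), c(8, 1))
  expect_equal(c(clin$time, clin$event), c(16, 1))  # closure lost at wk 28
  ## loss of closure triggers both relapse outcomes at the same time
  v2 <- visit_rows("P1", c(0, 12, 16), c(FALSE, TRUE, FALSE),
                   c(2, 0, 0), c(2, 0, 0))
  co2 <- mini_cohort(v2)
  expect_equal(derive_relapse(co2, "cpc")$time, 4)
  expect_equal(derive_relapse(co2, "clinical")$time, 4)
  ## censoring from the relapse baseline: remission wk 12, lost wk 40
  v3 <- visit_rows("P1", c(0, 12), c(FALSE, TRUE), c(2, 0), c(2, 0))
  co3 <- mini_cohort(v3, censor_week = 40, censor_reason = "lost")
  s3 <- derive_relapse(co3, "cpc")
  expect_equal(c(s3$time, s3$event), c(28, 0))
  ## no relapse sample without an achieved CPC remission
  v4 <- visit_rows("P1", c(0, 12), c(FALSE, TRUE), c(2, 1), c(2, 0))
  expect_null(derive_relapse(mini_cohort(v4), "cpc"))
})

test_that("lead-in shifting flags premature events and keeps identity at 0", {
  s <- data.frame(time = c(8, 3, 5), event = c(1, 1, 0))
  ## lead-in 0: identity
  s0 <- apply_lead_in(s, 0)
  expect_equal(s0$time_fitted, s$time)
  expect_equal(attr(s0, "leadin_violations"), 0)
  ## 4-week lead-in: t = 8 fits at 4; the week-3 event violates the window
  s4 <- apply_lead_in(s, 4)
  expect_equal(s4$time_fitted, c(4, 1e-3, 1))
  expect_equal(attr(s4, "leadin_violations"), 1)
  expect_error(apply_lead_in(s, -1), "non-negative")
})

test_that("outcome ordering invariants hold on generated cohorts", {
  cfg <- exp_cohort_config(n = 400, lambda_rem = 0.06, lambda_rel = 0.03,
                           seed = 43, visit_by = 2, followup = 200)
  co <- generate_cohort(cfg)
  ev <- derive_events(co)
  w <- stats::reshape(
    ev[, c("patient_id", "outcome", "time")],
    direction = "wide", idvar = "patient_id", timevar = "outcome")
  ## CPC remission cannot precede clinical remission
  both <- !is.na(w$time.CLIN_REMISSION) & !is.na(w$time.CPC_REMISSION)
  expect_true(all(w$time.CPC_REMISSION[both] >=
                    w$time.CLIN_REMISSION[both]))
  ## CPC relapse (superset trigger) cannot come after clinical relapse
  evn <- ev[ev$event == 1, ]
  wr <- stats::reshape(
    evn[, c("patient_id", "outcome", "time")],
    direction = "wide", idvar = "patient_id", timevar = "outcome")
  bothr <- !is.na(wr$time.CLIN_RELAPSE_FROM_CPC) &
    !is.na(wr$time.CPC_RELAPSE_FROM_CPC)
  expect_gt(sum(bothr), 10)
  expect_true(all(wr$time.CPC_RELAPSE_FROM_CPC[bothr] <=
                    wr$time.CLIN_RELAPSE_FROM_CPC[bothr]))
  ## one relapse sample per achieved CPC remission
  n_cpc_events <- sum(ev$outcome == "CPC_REMISSION" & ev$event == 1)
  expect_equal(sum(ev$outcome == "CPC_RELAPSE_FROM_CPC"), n_cpc_events)
})
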