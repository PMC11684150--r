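# shared fixtures: all inputs are built in code at test time

## minimal cohort from hand-written visit rows; every patient gets the
## baseline columns the derivation functions expect
mini_cohort <- function(visits, censor_week = NULL, censor_reason = NULL,
                        arm = NULL, study = NULL) {
  ids <- unique(visits$patient_id)
  n <- length(ids)
  bl <- data.frame(
    patient_id = ids,
    study = if (is.null(study)) rep("TRIAL", n) else rep_len(study, n),
    arm = if (is.null(arm)) rep("DVS", n) else rep_len(arm, n),
    age = seq(30, by = 1, length.out = n),
    stringsAsFactors = FALSE)
  if (!is.null(censor_week)) {
    bl$censor_week <- rep_len(censor_week, n)
    bl$censor_reason <- rep_len(censor_reason %||% "lost", n)
  }
  structure(list(baseline = bl, visits = visits, config = NULL),
            class = "cpf_cohort")
}

visit_rows <- function(patient_id, week, closed, pain = NA, discharge = NA) {
  data.frame(patient_id = patient_id, week = week, eo_all_closed = closed,
             pdai_pain = pain, pdai_discharge = discharge,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## an all-exponential generator configuration (constant hazards, no
## covariate effects) — the workhorse for closed-form oracle checks
exp_cohort_config <- function(n = 500, lambda_rem = 0.05,
                              lambda_rel = 0.02, seed = 1,
                              lead_in = 0, observation = "visit",
                              visit_by = 1, followup = 300,
                              missingness = list(), keep_latent = FALSE) {
  cohort_config(
    n_trial = n, n_rwe = 2, n_unassessed_trial = 0, n_unassessed_rwe = 0,
    n_trial_dvs = floor(n / 2),
    true_models = list(
      clin_remission = list(family = "exponential",
                            beta = c(intercept = log(lambda_rem))),
      cpc_remission = list(family = "exponential",
                           beta = c(intercept = log(lambda_rem))),
      clin_relapse = list(family = "exponential",
                          beta = c(intercept = log(lambda_rel))),
      cpc_relapse = list(family = "exponential",
                         beta = c(intercept = log(lambda_rel)))),
    visit_schedule = list(trial_weeks = seq(0, followup, by = visit_by),
                          rwe_gap_meanlog = log(8), rwe_gap_sdlog = 0.5,
                          followup_weeks = c(trial = followup,
                                             rwe = followup)),
    missingness = missingness,
    censoring = c(lost = 0, proctectomy = 0, death = 0),
    lead_in_weeks = lead_in, observation = observation,
    keep_latent = keep_latent, seed = seed)
}

## independent risk-set-by-risk-set two-sample statistic (unit or
## Peto-Peto weights), used as the oracle for two_sample_test()
brute_force_two_sample <- function(time, event, group, weights = "unit") {
  ut <- sort(unique(time[event == 1]))
  num <- 0; den <- 0
  ## left-continuous pooled KM for Peto-Peto weights
  pooled_km_left <- function(t) {
    s <- 1
    for (tt in ut[ut < t]) {
      n_t <- sum(time >= tt)
      d_t <- sum(time == tt & event == 1)
      s <- s * (1 - d_t / n_t)
    }
    s
  }
  for (tt in ut) {
    at_risk <- time >= tt
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & group == 1)
    d_t <- sum(time == tt & event == 1)
    d1_t <- sum(time == tt & event == 1 & group == 1)
    if (n_t < 2) next
    e1 <- d_t * n1_t / n_t
    v1 <- d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    w <- if (weights == "unit") 1 else pooled_km_left(tt)
    num <- num + w * (d1_t - e1)
    den <- den + w^2 * v1
  }
  num^2 / den
}
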