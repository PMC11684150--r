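#' Configuration for the synthetic two-study cohort generator
#'
#' Builds (and validates) the full parameter set of the generator: a
#' randomized trial arm ("TRIAL", both treatment arms, fixed visit grid)
#' and a real-world chart-review arm ("RWE", standard-of-care only,
#' irregular visits, heavy missingness in patient-reported scores). The
#' defaults emulate a pooled perianal-fistula analysis population: 212
#' enrolled trial patients of whom 12 lack a completed post-index
#' assessment (101 of the 200 assessable on active treatment), 386
#' real-world patients of whom 73 lack one, baseline covariates with the
#' published marginal summaries, 73.5% missing visit-level PDAI scores in
#' the real-world study versus 0.5% in the trial, and a 4-week lead-in
#' during which remission events are structurally absent.
#'
#' @param n_trial,n_rwe number of patients per study.
#' @param n_unassessed_trial,n_unassessed_rwe number of patients per study
#'   flagged as lacking any completed post-index clinical assessment (these
#'   are later removed by [apply_exclusions()]).
#' @param n_trial_dvs number of active-arm patients among the *assessable*
#'   trial patients (the real-world study is comparator-only).
#' @param covariate_model per-covariate distribution specification; see the
#'   default for the format (`type` "normal", "categorical", "binary" or
#'   "count1p"; parameters given per study as `c(trial = , rwe = )` or a
#'   `probs` list).
#' @param true_models named list over the four outcomes
#'   (`clin_remission`, `cpc_remission`, `clin_relapse`, `cpc_relapse`),
#'   each a list with `family`, location coefficients `beta`, shape
#'   coefficients `gamma` (names `"intercept"`, `"armDVS"`, or a covariate
#'   name) and optionally `Q` for the generalized gamma.
#' @param visit_schedule list with `trial_weeks` (fixed grid),
#'   `rwe_gap_meanlog`/`rwe_gap_sdlog` (log-normal inter-visit gaps) and
#'   `followup_weeks = c(trial = , rwe = )`.
#' @param missingness per-variable missing-probability list, each entry
#'   `c(trial = p, rwe = p)`; variables `pdai_pain`/`pdai_discharge` act on
#'   visit rows, all others on baseline columns.
#' @param censoring weekly rates `c(lost = , proctectomy = , death = )`.
#' @param lead_in_weeks non-negative lead-in applied to remission sojourns.
#' @param pdai_positive category probabilities (scores 0-3) of each PDAI
#'   element while symptomatic.
#' @param observation `"visit"` (interval observation at visits, the
#'   default) or `"exact"` (visits exactly at latent transition times, for
#'   oracle checks).
#' @param keep_latent keep the latent first-cycle event times as
#'   `latent_*` columns of the baseline table.
#' @param seed integer seed; generation is fully reproducible given it.
#' @return a validated object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_trial = 212, n_rwe = 386,
                          n_unassessed_trial = 12, n_unassessed_rwe = 73,
                          n_trial_dvs = 101,
                          covariate_model = default_covariate_model(),
                          true_models = default_true_models(),
                          visit_schedule = list(
                            trial_weeks = seq(0, 104, by = 4),
                            rwe_gap_meanlog = log(8), rwe_gap_sdlog = 0.5,
                            followup_weeks = c(trial = 104, rwe = 156)),
                          missingness = default_missingness(),
                          censoring = c(lost = 0.002, proctectomy = 5e-4,
                                        death = 2e-4),
                          lead_in_weeks = 4,
                          pdai_positive = c(0.12, 0.33, 0.37, 0.18),
                          observation = c("visit", "exact"),
                          keep_latent = FALSE,
                          seed = 1L) {
  cfg <- list(n_trial = n_trial, n_rwe = n_rwe,
              n_unassessed_trial = n_unassessed_trial,
              n_unassessed_rwe = n_unassessed_rwe,
              n_trial_dvs = n_trial_dvs,
              covariate_model = covariate_model,
              true_models = true_models,
              visit_schedule = visit_schedule,
              missingness = missingness,
              censoring = censoring,
              lead_in_weeks = lead_in_weeks,
              pdai_positive = pdai_positive,
              observation = match.arg(observation),
              keep_latent = keep_latent,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @export
default_covariate_model <- function() {
  list(
    age = list(type = "normal", mean = c(trial = 38.2, rwe = 37.9),
               sd = c(trial = 13.2, rwe = 13.4), min = 18),
    gender = list(type = "categorical", levels = c("male", "female"),
                  probs = list(trial = c(0.54, 0.46), rwe = c(0.52, 0.48))),
    ethnicity = list(type = "categorical",
                     levels = c("caucasian", "other"),
                     probs = list(trial = c(0.92, 0.08),
                                  rwe = c(0.98, 0.02))),
    weight = list(type = "normal", mean = c(trial = 72.2, rwe = 66.1),
                  sd = c(trial = 14.8, rwe = 14.3), min = 35),
    cd_duration = list(type = "normal", mean = c(trial = 11.4, rwe = 9.4),
                       sd = c(trial = 9.2, rwe = 8.9), min = 0),
    smoking = list(type = "categorical",
                   levels = c("current", "former", "never"),
                   probs = list(trial = c(0.44, 0.15, 0.41),
                                rwe = c(0.34, 0.17, 0.49))),
    luminal = list(type = "categorical",
                   levels = c("mild_inactive", "moderate", "severe"),
                   probs = list(trial = c(1, 0, 0),
                                rwe = c(0.58, 0.36, 0.06))),
    n_io = list(type = "count1p", lambda = c(trial = 0.2, rwe = 0.3)),
    n_eo = list(type = "count1p", lambda = c(trial = 0.5, rwe = 0.5)),
    prior_abx = list(type = "binary", p = c(trial = 0.745, rwe = 0.23)),
    prior_bio = list(type = "binary", p = c(trial = 0.795, rwe = 0.46)),
    prior_imm = list(type = "binary", p = c(trial = 0.775, rwe = 0.68)),
    cdai = list(type = "normal", mean = c(trial = 90.7, rwe = 172.9),
                sd = c(trial = 52.0, rwe = 90.0), min = 0),
    pdai_pain_bl = list(type = "categorical", levels = 0:3,
                        probs = list(trial = c(0.25, 0.40, 0.25, 0.10),
                                     rwe = c(0.10, 0.25, 0.40, 0.25))),
    pdai_discharge_bl = list(type = "categorical", levels = 0:3,
                             probs = list(trial = c(0.15, 0.35, 0.35, 0.15),
                                          rwe = c(0.08, 0.22, 0.42, 0.28)))
  )
}

#' @rdname cohort_config
#' @export
default_true_models <- function() {
  ## remission follows a defective Gompertz (negative, arm-dependent shape):
  ## occupancy rises quickly then plateaus, as long-term remission
  ## fractions do in this indication; relapse is Weibull with a slower
  ## clock on active treatment
  list(
    clin_remission = list(family = "gompertz",
                          beta = c(intercept = -3.65, armDVS = 0.7,
                                   cd_duration = -0.005),
                          gamma = c(intercept = -0.012, armDVS = -0.02)),
    cpc_remission = list(family = "gompertz",
                         beta = c(intercept = -3.8, armDVS = 0.75,
                                  cd_duration = -0.005),
                         gamma = c(intercept = -0.012, armDVS = -0.025)),
    clin_relapse = list(family = "weibull",
                        beta = c(intercept = 4.9, armDVS = 0.5),
                        gamma = c(intercept = -0.10)),
    cpc_relapse = list(family = "weibull",
                       beta = c(intercept = 4.6, armDVS = 0.5),
                       gamma = c(intercept = -0.10))
  )
}

#' @rdname cohort_config
#' @export
default_missingness <- function() {
  list(
    pdai_pain = c(trial = 0.005, rwe = 0.735),
    pdai_discharge = c(trial = 0.005, rwe = 0.735),
    weight = c(trial = 0.010, rwe = 0.070),
    cd_duration = c(trial = 0.005, rwe = 0.016),
    smoking = c(trial = 0.805, rwe = 0.006),
    luminal = c(trial = 0, rwe = 0.064),
    n_eo = c(trial = 0.015, rwe = 0.026),
    cdai = c(trial = 0.010, rwe = 0.757),
    pdai_pain_bl = c(trial = 0.005, rwe = 0.728),
    pdai_discharge_bl = c(trial = 0.005, rwe = 0.744)
  )
}

.outcomes4 <- c("clin_remission", "cpc_remission",
                "clin_relapse", "cpc_relapse")

#' @rdname cohort_config
#' @param config object to validate.
#' @export
validate_cohort_config <- function(config) {
  chk <- function(cond, field)
    if (!cond) stop("invalid cohort config field: ", field, call. = FALSE)
  chk(config$n_trial > 0, "n_trial")
  chk(config$n_rwe > 0, "n_rwe")
  chk(config$n_unassessed_trial >= 0 &&
        config$n_unassessed_trial < config$n_trial, "n_unassessed_trial")
  chk(config$n_unassessed_rwe >= 0 &&
        config$n_unassessed_rwe < config$n_rwe, "n_unassessed_rwe")
  chk(config$n_trial_dvs >= 0 &&
        config$n_trial_dvs <= config$n_trial - config$n_unassessed_trial,
      "n_trial_dvs")
  chk(config$lead_in_weeks >= 0, "lead_in_weeks")
  chk(all(unlist(config$missingness) >= 0) &&
        all(unlist(config$missingness) <= 1), "missingness")
  chk(all(config$censoring >= 0), "censoring")
  chk(all(names(config$true_models) %in% .outcomes4) &&
        all(.outcomes4 %in% names(config$true_models)), "true_models")
  for (nm in names(config$true_models)) {
    tm <- config$true_models[[nm]]
    chk(!is.null(tm$family) && tm$family %in% .ps_families,
        paste0("true_models$", nm, "$family"))
    chk(!is.null(tm$beta) && "intercept" %in% names(tm$beta),
        paste0("true_models$", nm, "$beta"))
  }
  pp <- config$pdai_positive
  chk(length(pp) == 4 && all(pp >= 0) && abs(sum(pp) - 1) < 1e-8,
      "pdai_positive")
  invisible(config)
}

## linear predictor for a true model over the baseline table
.true_lp <- function(coefs, baseline) {
  lp <- rep(0, nrow(baseline))
  for (nm in names(coefs)) {
    v <- coefs[[nm]]
    if (nm == "intercept") lp <- lp + v
    else if (nm == "armDVS") lp <- lp + v * (baseline$arm == "DVS")
    else if (nm %in% names(baseline)) {
      x <- baseline[[nm]]
      if (!is.numeric(x)) stop("true-model covariate not numeric: ", nm)
      lp <- lp + v * x
    } else stop("unknown covariate in true model: ", nm)
  }
  lp
}

.true_draw <- function(model, baseline, n, u = stats::runif(n)) {
  mu <- .true_lp(model$beta, baseline)
  fam <- model$family
  info <- ps_family_info(fam)
  anc <- NULL
  if (length(info$anc_names) > 0) {
    eta <- .true_lp(model$gamma %||% c(intercept = 0), baseline)
    a1 <- if (info$links[1] == "log") exp(eta) else eta
    anc <- if (fam == "gengamma") cbind(a1, model$Q %||% 1) else cbind(a1)
  }
  ps_rtime(u, fam, mu, anc)
}

.draw_covariate <- function(spec, study, n) {
  key <- if (study == "TRIAL") "trial" else "rwe"
  switch(spec$type,
    normal = {
      v <- stats::rnorm(n, spec$mean[[key]], spec$sd[[key]])
      if (!is.null(spec$min)) v <- pmax(v, spec$min)
      round(v, 1)
    },
    categorical = {
      lev <- spec$levels
      s <- sample(seq_along(lev), n, replace = TRUE, prob = spec$probs[[key]])
      if (is.numeric(lev)) lev[s] else factor(lev[s], levels = lev)
    },
    binary = as.integer(stats::runif(n) < spec$p[[key]]),
    count1p = 1L + stats::rpois(n, spec$lambda[[key]]),
    stop("unknown covariate type: ", spec$type))
}

#' Generate a synthetic two-study cohort
#'
#' Draws baseline covariates per study from the configured marginal
#' distributions, assigns arms (trial: randomized; real-world study:
#' comparator only), simulates each patient's latent relapsing-remitting
#' event history from the configured true parametric models (covariate
#' effects entering through the location and shape linear predictors, clock
#' reset at every state entry, remission sojourns shifted by the lead-in),
#' samples that latent process at the study's visit schedule (interval
#' observation: a state change is detected at the first visit at which it
#' holds), applies censoring (loss to follow-up, proctectomy, death), drops
#' post-index assessments for the flagged "unassessed" patients, and finally
#' applies the configured missingness.
#'
#' @param config a [cohort_config()] object.
#' @return an object of class `"cpf_cohort"`: a list with `baseline` (one
#'   row per patient), `visits` (one row per visit: `patient_id`, `week`,
#'   `eo_all_closed`, `pdai_pain`, `pdai_discharge`) and the `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  n <- cfg$n_trial + cfg$n_rwe
  study <- rep(c("TRIAL", "RWE"), c(cfg$n_trial, cfg$n_rwe))
  id <- sprintf("P%04d", seq_len(n))

  ## flagged unassessed patients: first n_unassessed of each study
  unassessed <- c(seq_len(cfg$n_unassessed_trial),
                  cfg$n_trial + seq_len(cfg$n_unassessed_rwe))
  assessable_trial <- setdiff(seq_len(cfg$n_trial),
                              seq_len(cfg$n_unassessed_trial))
  arm <- rep("SOC", n)
  arm[assessable_trial[seq_len(cfg$n_trial_dvs)]] <- "DVS"
  ## unassessed trial patients split evenly across arms
  if (cfg$n_unassessed_trial > 1)
    arm[seq_len(cfg$n_unassessed_trial %/% 2)] <- "DVS"

  baseline <- data.frame(patient_id = id, study = study, arm = arm,
                         stringsAsFactors = FALSE)
  for (nm in names(cfg$covariate_model)) {
    spec <- cfg$covariate_model[[nm]]
    v <- rep(NA, n)
    for (st in c("TRIAL", "RWE")) {
      idx <- study == st
      v[idx] <- .draw_covariate(spec, st, sum(idx))
    }
    if (spec$type == "categorical" && !is.numeric(spec$levels))
      v <- factor(spec$levels[as.integer(v)], levels = spec$levels)
    baseline[[nm]] <- v
  }

  ## censoring: competing exponential causes + administrative end
  cr <- cfg$censoring
  fup <- ifelse(study == "TRIAL",
                cfg$visit_schedule$followup_weeks[["trial"]],
                cfg$visit_schedule$followup_weeks[["rwe"]])
  ctimes <- sapply(cr, function(r)
    if (r > 0) stats::rexp(n, r) else rep(Inf, n))
  cmin <- apply(ctimes, 1, min)
  creason <- names(cr)[apply(ctimes, 1, which.min)]
  censor_week <- pmin(cmin, fup)
  censor_reason <- ifelse(cmin < fup, creason, "end_of_followup")
  baseline$censor_week <- round(censor_week, 2)
  baseline$censor_reason <- censor_reason

  ## latent relapsing-remitting cycles
  li <- cfg$lead_in_weeks
  cyc <- list()
  cur <- rep(0, n)
  active <- rep(TRUE, n)
  guard <- 0L
  while (any(active) && guard < 60L) {
    guard <- guard + 1L
    idx <- which(active)
    bl <- baseline[idx, , drop = FALSE]
    m <- length(idx)
    ## comonotone coupling within each pair: the clinical and CPC times
    ## share one latent severity uniform, so each marginal follows its
    ## configured model while the clinical-only gap stays realistic
    u_rem <- stats::runif(m); u_rel <- stats::runif(m)
    A <- li + .true_draw(cfg$true_models$clin_remission, bl, m, u_rem)
    B <- li + .true_draw(cfg$true_models$cpc_remission, bl, m, u_rem)
    U <- .true_draw(cfg$true_models$clin_relapse, bl, m, u_rel)
    W <- .true_draw(cfg$true_models$cpc_relapse, bl, m, u_rel)
    s <- cur[idx]
    R <- s + pmax(A, B)
    cyc[[guard]] <- data.frame(
      i = idx, start = s,
      t_clin_rem = s + A, t_cpc_rem = R,
      t_cpc_rel = R + pmin(U, W), t_clin_rel = R + U)
    cur[idx] <- R + U
    active[idx] <- cur[idx] < censor_week[idx] & is.finite(cur[idx])
  }
  cycles <- do.call(rbind, cyc)
  cycles <- cycles[order(cycles$i, cycles$start), ]

  first <- cycles[!duplicated(cycles$i), ]
  if (cfg$keep_latent) {
    baseline$latent_clin_rem <- first$t_clin_rem[match(seq_len(n), first$i)]
    baseline$latent_cpc_rem <- first$t_cpc_rem[match(seq_len(n), first$i)]
    baseline$latent_cpc_rel <- first$t_cpc_rel[match(seq_len(n), first$i)]
    baseline$latent_clin_rel <- first$t_clin_rel[match(seq_len(n), first$i)]
  }

  ## visit schedules
  vs <- cfg$visit_schedule
  visit_list <- vector("list", n)
  for (i in seq_len(n)) {
    if (cfg$observation == "exact") {
      ci <- cycles[cycles$i == i, ]
      w <- sort(unique(c(0, unlist(ci[, c("t_clin_rem", "t_cpc_rem",
                                          "t_cpc_rel", "t_clin_rel")]))))
      w <- w[is.finite(w)]
    } else if (study[i] == "TRIAL") {
      w <- vs$trial_weeks
    } else {
      gaps <- stats::rlnorm(200, vs$rwe_gap_meanlog, vs$rwe_gap_sdlog)
      w <- c(0, cumsum(gaps))
      w <- round(w[w <= fup[i]], 1)
    }
    w <- w[w <= censor_week[i]]
    if (length(w) == 0 || w[1] != 0) w <- c(0, w)
    ## an assessable patient always gets a closing assessment at the end of
    ## observation, even when censored before the first scheduled visit
    if (!(i %in% unassessed) && !any(w > 0))
      w <- c(w, max(censor_week[i], 0.1))
    visit_list[[i]] <- w
  }
  nv <- lengths(visit_list)
  visits <- data.frame(
    i = rep(seq_len(n), nv),
    week = unlist(visit_list))

  ## observed state at each visit from the latent cycles
  closed <- logical(nrow(visits))
  pdai0 <- logical(nrow(visits))
  cyc_by_i <- split(cycles, cycles$i)
  v_by_i <- split(seq_len(nrow(visits)), visits$i)
  for (i in seq_len(n)) {
    rows <- v_by_i[[as.character(i)]]
    if (is.null(rows)) next
    w <- visits$week[rows]
    ci <- cyc_by_i[[as.character(i)]]
    cl <- rep(FALSE, length(w)); p0 <- rep(FALSE, length(w))
    for (r in seq_len(nrow(ci))) {
      cl <- cl | (w >= ci$t_clin_rem[r] & w < ci$t_clin_rel[r])
      p0 <- p0 | (w >= ci$t_cpc_rem[r] & w < ci$t_cpc_rel[r])
    }
    closed[rows] <- cl
    pdai0[rows] <- p0
  }

  ## PDAI elements: 0 in CPC remission, symptomatic draw otherwise
  npos <- sum(!pdai0)
  pain <- integer(nrow(visits)); disch <- integer(nrow(visits))
  pain[!pdai0] <- sample(0:3, npos, replace = TRUE, prob = cfg$pdai_positive)
  disch[!pdai0] <- sample(0:3, npos, replace = TRUE,
                          prob = cfg$pdai_positive)
  both0 <- !pdai0 & pain == 0 & disch == 0
  disch[both0] <- 1L  # symptomatic state: not both elements zero
  ## week-0 row reports the baseline scores
  w0 <- visits$week == 0
  pain[w0] <- as.integer(as.character(baseline$pdai_pain_bl[visits$i[w0]]))
  disch[w0] <- as.integer(as.character(
    baseline$pdai_discharge_bl[visits$i[w0]]))
  closed[w0] <- FALSE

  visits$eo_all_closed <- closed
  visits$pdai_pain <- pain
  visits$pdai_discharge <- disch

  ## unassessed patients contribute no post-index assessments
  visits <- visits[!(visits$i %in% unassessed & visits$week > 0), ]
  visits$patient_id <- id[visits$i]
  visits <- visits[, c("patient_id", "week", "eo_all_closed",
                       "pdai_pain", "pdai_discharge")]
  rownames(visits) <- NULL

  out <- structure(list(baseline = baseline, visits = visits, config = cfg),
                   class = "cpf_cohort")
  if (length(cfg$missingness) > 0)
    out <- inject_missingness(out, cfg$missingness,
                              seed = child_seed(cfg$seed, 7L))
  out
}

#' @export
print.cpf_cohort <- function(x, ...) {
  cat("Synthetic two-study cohort:", nrow(x$baseline), "patients,",
      nrow(x$visits), "visit rows\n")
  print(table(x$baseline$study, x$baseline$arm))
  invisible(x)
}

#' Inject missing values into a cohort
#'
#' Sets targeted values to `NA`, independently per value. Under the default
#' MCAR mechanism each targeted value is missing with its configured
#' probability; under MAR the probability depends on the patient's observed
#' age (logit-linear, centred at the cohort mean), emulating
#' covariate-dependent ascertainment.
#'
#' @param cohort a `"cpf_cohort"` object.
#' @param spec named list; each element `c(trial = p, rwe = p)`. Names
#'   `pdai_pain`/`pdai_discharge` target post-index visit rows; other names
#'   must be baseline columns.
#' @param seed integer seed.
#' @param mechanism `"mcar"` or `"mar"`.
#' @param mar_coef log-odds change in missingness per SD of age (MAR only).
#' @return the cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, spec, seed = 1L,
                               mechanism = c("mcar", "mar"),
                               mar_coef = 0.5) {
  mechanism <- match.arg(mechanism)
  stopifnot(inherits(cohort, "cpf_cohort"))
  if (any(unlist(spec) < 0 | unlist(spec) > 1))
    stop("missingness probabilities must be in [0, 1]")
  visit_vars <- c("pdai_pain", "pdai_discharge")
  for (nm in names(spec)) {
    if (!(nm %in% visit_vars) && !(nm %in% names(cohort$baseline)))
      stop("unknown variable in missingness spec: ", nm)
  }
  with_seed(seed, {
    bl <- cohort$baseline; vis <- cohort$visits
    agez <- as.numeric(scale(bl$age))
    for (nm in names(spec)) {
      p <- spec[[nm]]
      if (nm %in% visit_vars) {
        idx <- vis$week > 0  # week-0 scores are the baseline measurement
        st <- bl$study[match(vis$patient_id, bl$patient_id)]
        pr <- ifelse(st == "TRIAL", p[["trial"]], p[["rwe"]])
        if (mechanism == "mar") {
          az <- agez[match(vis$patient_id, bl$patient_id)]
          boundary <- pr %in% c(0, 1)
          adj <- stats::plogis(stats::qlogis(pmin(pmax(pr, 1e-12),
                                                  1 - 1e-12)) +
                                 mar_coef * az)
          pr <- ifelse(boundary, pr, adj)
        }
        hit <- idx & stats::runif(nrow(vis)) < pr
        vis[[nm]][hit] <- NA
      } else {
        pr <- ifelse(bl$study == "TRIAL", p[["trial"]], p[["rwe"]])
        if (mechanism == "mar") {
          boundary <- pr %in% c(0, 1)
          adj <- stats::plogis(stats::qlogis(pmin(pmax(pr, 1e-12),
                                                  1 - 1e-12)) +
                                 mar_coef * agez)
          pr <- ifelse(boundary, pr, adj)
        }
        hit <- stats::runif(nrow(bl)) < pr
        bl[[nm]][hit] <- NA
      }
    }
    cohort$baseline <- bl; cohort$visits <- vis
    cohort
  })
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort()` writes `baseline.csv`, `visits.csv` and a JSON sidecar
#' echoing the generator configuration and seed; `read_cohort()` restores
#' the object.
#'
#' @param cohort a `"cpf_cohort"` object.
#' @param dir directory to write to (created if needed).
#' @return `write_cohort()` the directory invisibly; `read_cohort()` a
#'   `"cpf_cohort"` object.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$baseline, file.path(dir, "baseline.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$visits, file.path(dir, "visits.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  cfg$covariate_model <- NULL  # not JSON-stable; re-create from code
  jsonlite::write_json(cfg, file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  bl <- utils::read.csv(file.path(dir, "baseline.csv"),
                        stringsAsFactors = FALSE)
  vis <- utils::read.csv(file.path(dir, "visits.csv"),
                         stringsAsFactors = FALSE)
  structure(list(baseline = bl, visits = vis, config = NULL),
            class = "cpf_cohort")
}
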