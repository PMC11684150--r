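## covariate columns carried onto survival samples when present
.cov_schema <- c("age", "gender", "ethnicity", "weight", "cd_duration",
                 "smoking", "luminal", "n_io", "n_eo", "prior_abx",
                 "prior_bio", "prior_imm", "cdai",
                 "pdai_pain_bl", "pdai_discharge_bl")

## end of observation for a patient: the censoring event when recorded,
## otherwise the last visit
.obs_end <- function(bl_row, last_visit) {
  cw <- bl_row$censor_week
  if (!is.null(cw) && length(cw) == 1 && !is.na(cw)) cw else last_visit
}

.sample_row <- function(bl_row, outcome, time, event) {
  out <- data.frame(patient_id = bl_row$patient_id, outcome = outcome,
                    time = time, event = event,
                    arm = bl_row$arm, study = bl_row$study,
                    stringsAsFactors = FALSE)
  for (v in .cov_schema)
    if (v %in% names(bl_row)) out[[v]] <- bl_row[[v]]
  out
}

#' Derive time-to-remission samples from visit records
#'
#' Walks each patient's post-index visits (week > 0; the week-0 visit is
#' the baseline assessment) and emits one right-censored observation per
#' patient. The qualifying event is the first visit at which all
#' baseline-draining external openings are closed (`definition =
#' "clinical"`), additionally requiring a PDAI pain score of 0 *and* a PDAI
#' discharge score of 0 at the same visit (`definition = "cpc"`). A missing
#' component never qualifies (upstream imputation decides borderline
#' visits). Patients with no qualifying event are censored at the end of
#' observation (censoring event — loss to follow-up, proctectomy or death —
#' when recorded, otherwise the last visit). Patients are removed after
#' their first event. Records with no post-index visits are dropped with a
#' warning.
#'
#' @param cohort a `"cpf_cohort"`.
#' @param definition `"clinical"` or `"cpc"`.
#' @return a data frame of survival samples: `patient_id`, `outcome`,
#'   `time` (weeks since treatment initiation), `event` (0/1), `arm`,
#'   `study` and the shared covariate columns.
#' @export
derive_remission <- function(cohort, definition = c("clinical", "cpc")) {
  definition <- match.arg(definition)
  outcome <- if (definition == "clinical") "CLIN_REMISSION" else
    "CPC_REMISSION"
  bl <- cohort$baseline
  vis <- cohort$visits[cohort$visits$week > 0, , drop = FALSE]
  vis <- vis[order(vis$patient_id, vis$week), ]
  v_by <- split(vis, vis$patient_id)
  rows <- vector("list", nrow(bl)); nodata <- 0L
  for (i in seq_len(nrow(bl))) {
    blr <- bl[i, , drop = FALSE]
    pv <- v_by[[blr$patient_id]]
    if (is.null(pv) || nrow(pv) == 0) { nodata <- nodata + 1L; next }
    qual <- !is.na(pv$eo_all_closed) & pv$eo_all_closed
    if (definition == "cpc")
      qual <- qual & !is.na(pv$pdai_pain) & pv$pdai_pain == 0 &
        !is.na(pv$pdai_discharge) & pv$pdai_discharge == 0
    if (any(qual)) {
      rows[[i]] <- .sample_row(blr, outcome, pv$week[which(qual)[1]], 1L)
    } else {
      tc <- .obs_end(blr, max(pv$week))
      if (tc > 0) rows[[i]] <- .sample_row(blr, outcome, tc, 0L)
    }
  }
  if (nodata > 0)
    warning(nodata, " record(s) with no post-index visits dropped")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derive time-to-relapse samples from visit records
#'
#' The at-risk population is the set of patients with an observed CPC
#' remission (closure plus PDAI pain 0 and discharge 0); the outcome-
#' specific baseline is that first CPC-remission visit, and the clock is
#' reset to it. The qualifying event is the first later visit showing loss
#' of closure (`definition = "clinical"`), or loss of closure *or* a PDAI
#' pain or discharge score above 0 (`definition = "cpc"`). Censoring as in
#' [derive_remission()], measured from the new baseline.
#'
#' @inheritParams derive_remission
#' @return a data frame of survival samples (`outcome`
#'   `"CLIN_RELAPSE_FROM_CPC"` or `"CPC_RELAPSE_FROM_CPC"`).
#' @export
derive_relapse <- function(cohort, definition = c("clinical", "cpc")) {
  definition <- match.arg(definition)
  outcome <- if (definition == "clinical") "CLIN_RELAPSE_FROM_CPC" else
    "CPC_RELAPSE_FROM_CPC"
  bl <- cohort$baseline
  vis <- cohort$visits[cohort$visits$week > 0, , drop = FALSE]
  vis <- vis[order(vis$patient_id, vis$week), ]
  v_by <- split(vis, vis$patient_id)
  rows <- list()
  for (i in seq_len(nrow(bl))) {
    blr <- bl[i, , drop = FALSE]
    pv <- v_by[[blr$patient_id]]
    if (is.null(pv) || nrow(pv) == 0) next
    rem <- !is.na(pv$eo_all_closed) & pv$eo_all_closed &
      !is.na(pv$pdai_pain) & pv$pdai_pain == 0 &
      !is.na(pv$pdai_discharge) & pv$pdai_discharge == 0
    if (!any(rem)) next  # relapse defined only from achieved CPC remission
    t0 <- pv$week[which(rem)[1]]
    after <- pv[pv$week > t0, , drop = FALSE]
    loss_closure <- !is.na(after$eo_all_closed) & !after$eo_all_closed
    qual <- if (definition == "clinical") loss_closure else
      loss_closure |
        (!is.na(after$pdai_pain) & after$pdai_pain > 0) |
        (!is.na(after$pdai_discharge) & after$pdai_discharge > 0)
    if (any(qual)) {
      rows[[length(rows) + 1L]] <-
        .sample_row(blr, outcome, after$week[which(qual)[1]] - t0, 1L)
    } else {
      ## zero-length post-remission follow-up still contributes a
      ## (vanishingly short) censored sample, so that every achieved CPC
      ## remission yields exactly one relapse sample
      tc <- max(.obs_end(blr, max(pv$week)) - t0, 1e-3)
      rows[[length(rows) + 1L]] <- .sample_row(blr, outcome, tc, 0L)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derive all four outcomes at once
#'
#' @inheritParams derive_remission
#' @return one long data frame stacking the clinical/CPC remission and
#'   relapse samples.
#' @export
derive_events <- function(cohort) {
  rbind(derive_remission(cohort, "clinical"),
        derive_remission(cohort, "cpc"),
        derive_relapse(cohort, "clinical"),
        derive_relapse(cohort, "cpc"))
}

#' Shift survival samples by a lead-in window
#'
#' For parametric fitting with a lead-in — an initial window in which
#' events are structurally absent — the likelihood sees shifted times
#' \eqn{t' = \max(t - \text{lead\_in}, \epsilon)}. Events at or before the
#' lead-in contradict that premise and are counted in the
#' `"leadin_violations"` attribute. Reported curves are re-shifted so that
#' S(t) = 1 before the lead-in ends (see [predict.psfit()]).
#'
#' @param samples a survival-sample data frame with `time` and `event`.
#' @param lead_in_weeks non-negative lead-in in weeks.
#' @param eps floor for shifted times.
#' @return `samples` with a `time_fitted` column and attribute
#'   `leadin_violations`.
#' @export
apply_lead_in <- function(samples, lead_in_weeks, eps = 1e-3) {
  if (lead_in_weeks < 0) stop("lead_in_weeks must be non-negative")
  samples$time_fitted <- pmax(samples$time - lead_in_weeks, eps)
  viol <- sum(samples$event == 1 & samples$time <= lead_in_weeks)
  attr(samples, "leadin_violations") <- viol
  samples
}
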