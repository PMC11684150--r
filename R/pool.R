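#' Align variable names and codings across study tables
#'
#' Maps each study's baseline table onto one shared schema. The mapping
#' gives, per target variable, the source column name in each study and an
#' optional value recoding per study; value recodings must be bijective
#' (no two source codes may collapse onto one target code). Variables
#' present in only one study are excluded from the shared covariate list
#' with a warning, as are unmapped source columns — only covariates shared
#' by all sources enter the pooled analyses.
#'
#' @param tables named list of data frames, one per study/source.
#' @param mapping named list: `target = list(sources = c(src1 = "col", ...),
#'   values = list(src1 = c(code = "target_code", ...)))`; `values` may be
#'   omitted for numeric pass-through. An identity mapping may be given as
#'   `target = list()` when all sources already use the target name.
#' @param keep columns copied through unmapped (identifiers etc.),
#'   default `c("patient_id")`.
#' @return one data frame in the shared schema with a `source` column.
#' @export
align_variables <- function(tables, mapping, keep = "patient_id") {
  stopifnot(is.list(tables), length(tables) >= 1, !is.null(names(tables)))
  src_names <- names(tables)
  shared <- character(0)
  out_cols <- list()
  for (tgt in names(mapping)) {
    m <- mapping[[tgt]]
    srcs <- m$sources %||% stats::setNames(rep(tgt, length(src_names)),
                                           src_names)
    present <- vapply(src_names, function(s)
      !is.na(srcs[s]) && srcs[[s]] %in% names(tables[[s]]), TRUE)
    if (!all(present)) {
      warning("variable '", tgt, "' not present in all sources; excluded ",
              "from the shared covariate list")
      next
    }
    vals <- lapply(src_names, function(s) {
      v <- tables[[s]][[srcs[[s]]]]
      vm <- m$values[[s]]
      if (!is.null(vm)) {
        if (anyDuplicated(vm))
          stop("value mapping for '", tgt, "' in source '", s,
               "' is not bijective")
        v2 <- vm[as.character(v)]
        if (any(is.na(v2) & !is.na(v)))
          stop("unmapped value(s) for '", tgt, "' in source '", s, "'")
        v <- unname(v2)
      }
      v
    })
    cls <- vapply(vals, function(v) class(v)[1], "")
    num <- vapply(vals, is.numeric, TRUE)
    if (length(unique(num)) > 1)
      stop("conflicting mapping for '", tgt,
           "': incompatible types across sources (",
           paste(cls, collapse = " vs "), ")")
    out_cols[[tgt]] <- vals
    shared <- c(shared, tgt)
  }
  dropped <- unlist(lapply(src_names, function(s) {
    used <- c(keep, vapply(names(mapping), function(tgt) {
      srcs <- mapping[[tgt]]$sources
      if (is.null(srcs) || is.na(srcs[s])) tgt else unname(srcs[s])
    }, ""))
    setdiff(names(tables[[s]]), used)
  }))
  if (length(dropped) > 0)
    warning("unmapped source variable(s) dropped: ",
            paste(unique(dropped), collapse = ", "))
  rows <- lapply(seq_along(src_names), function(si) {
    s <- src_names[si]
    d <- data.frame(source = s, stringsAsFactors = FALSE)
    d <- d[rep(1, nrow(tables[[s]])), , drop = FALSE]
    for (kc in keep)
      if (kc %in% names(tables[[s]])) d[[kc]] <- tables[[s]][[kc]]
    for (tgt in shared) d[[tgt]] <- out_cols[[tgt]][[si]]
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Link trial and follow-up records into one timeline per patient
#'
#' Patients in a follow-up chart review of trial participants are linked to
#' their trial record by identifier. The trial record is the primary source
#' wherever follow-up windows overlap: follow-up visits are appended only
#' after the trial's last follow-up week; earlier follow-up visits are
#' dropped.
#'
#' @param trial a `"cpf_cohort"` (or list with `baseline`/`visits`).
#' @param followup a cohort of follow-up records on the same identifier
#'   space; every follow-up patient must exist in the trial
#'   (orphans are an error listing the offending ids).
#' @return a `"cpf_cohort"` with merged visit timelines; baseline rows are
#'   taken from the trial.
#' @export
link_and_resolve <- function(trial, followup) {
  orphans <- setdiff(unique(followup$baseline$patient_id),
                     trial$baseline$patient_id)
  if (length(orphans) > 0)
    stop("follow-up record(s) with no matching trial id: ",
         paste(orphans, collapse = ", "))
  last_week <- tapply(trial$visits$week, trial$visits$patient_id, max)
  fv <- followup$visits
  cutoff <- last_week[fv$patient_id]
  cutoff[is.na(cutoff)] <- -Inf  # linked patient with no trial visits
  fv <- fv[fv$week > cutoff, , drop = FALSE]
  vis <- rbind(trial$visits, fv)
  vis <- vis[order(vis$patient_id, vis$week), ]
  rownames(vis) <- NULL
  structure(list(baseline = trial$baseline, visits = vis,
                 config = trial$config),
            class = "cpf_cohort")
}

#' Apply the post-index assessment exclusion and form the analysis sets
#'
#' A patient contributes to the pooled analysis only with at least one
#' completed post-index clinical assessment, operationalized as one or more
#' visit rows after week 0 with a non-missing external-opening closure
#' status. Retained patients are partitioned into the active-treatment
#' (DVS) and comparator (SoC/placebo) analysis sets.
#'
#' @param cohort a `"cpf_cohort"` (possibly already pooled; the operation
#'   is idempotent).
#' @return an object of class `"pooled_sets"`: list with `dvs` and `soc`
#'   (each `baseline` + `visits`), the combined retained `cohort`, and a
#'   `retention` table of per-study input/excluded/retained counts.
#' @export
apply_exclusions <- function(cohort) {
  if (inherits(cohort, "pooled_sets")) cohort <- cohort$cohort
  bl <- cohort$baseline; vis <- cohort$visits
  assessed_ids <- unique(vis$patient_id[vis$week > 0 &
                                          !is.na(vis$eo_all_closed)])
  bl$has_post_index_assessment <- bl$patient_id %in% assessed_ids
  keep <- bl$has_post_index_assessment
  retention <- do.call(rbind, lapply(split(keep, bl$study), function(k)
    data.frame(n_input = length(k), n_excluded = sum(!k),
               n_retained = sum(k))))
  retention <- cbind(study = rownames(retention), retention)
  rownames(retention) <- NULL
  blr <- bl[keep, , drop = FALSE]
  visr <- vis[vis$patient_id %in% blr$patient_id, , drop = FALSE]
  if (nrow(blr) == 0)
    message("no patients retained after the assessment exclusion")
  subset_cohort <- function(ids) {
    structure(list(baseline = blr[blr$patient_id %in% ids, , drop = FALSE],
                   visits = visr[visr$patient_id %in% ids, , drop = FALSE],
                   config = cohort$config),
              class = "cpf_cohort")
  }
  out <- list(
    dvs = subset_cohort(blr$patient_id[blr$arm == "DVS"]),
    soc = subset_cohort(blr$patient_id[blr$arm != "DVS"]),
    cohort = structure(list(baseline = blr, visits = visr,
                            config = cohort$config), class = "cpf_cohort"),
    retention = retention)
  class(out) <- "pooled_sets"
  out
}

#' @export
print.pooled_sets <- function(x, ...) {
  cat("Pooled analysis sets\n")
  print(x$retention, row.names = FALSE)
  cat("Retained:", nrow(x$cohort$baseline), "patients (",
      nrow(x$dvs$baseline), "DVS /", nrow(x$soc$baseline), "SoC )\n")
  invisible(x)
}
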