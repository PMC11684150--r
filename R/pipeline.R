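#' Pipeline configuration
#'
#' Single configuration object driving the end-to-end analysis:
#' generate (or read) the two-study cohort, pool and apply exclusions,
#' multiply impute, derive the four outcomes, run KM and two-sample tests,
#' fit the five parametric families with location and shape covariates,
#' select models by AIC, extrapolate with the semi-Markov engine, and
#' report remission percentages by month. The defaults reproduce the
#' standard analysis shape: four outcomes, five families, 4-week lead-in,
#' 48-month horizon.
#'
#' @param outdir run directory (created).
#' @param cohort a [cohort_config()], or a directory containing a cohort
#'   written by [write_cohort()].
#' @param m number of imputation completions.
#' @param outcomes outcomes to analyse.
#' @param families parametric families to fit.
#' @param location right-hand-side formula for the location covariates.
#' @param shape right-hand-side formula for the shape covariates.
#' @param lead_in_weeks lead-in for remission fits (relapse fits use 0:
#'   the lead-in reflects post-treatment assessment absence, which does not
#'   apply to the relapse clock).
#' @param horizon_months extrapolation horizon.
#' @param engine `"renewal"` (deterministic) or `"microsim"`.
#' @param n_sim microsimulation size (microsim engine only).
#' @param report_months months tabulated in the report.
#' @param seed master seed; every stage derives its own child seed.
#' @return a validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outdir,
                            cohort = cohort_config(),
                            m = 5,
                            outcomes = c("CLIN_REMISSION", "CPC_REMISSION",
                                         "CLIN_RELAPSE_FROM_CPC",
                                         "CPC_RELAPSE_FROM_CPC"),
                            families = c("weibull", "gompertz", "gengamma",
                                         "llogis", "lnorm"),
                            location = ~ arm + age + cd_duration,
                            shape = ~ arm,
                            lead_in_weeks = 4,
                            horizon_months = 48,
                            engine = c("renewal", "microsim"),
                            n_sim = 20000,
                            report_months = c(0, 8, 24, 48),
                            seed = 1L) {
  engine <- match.arg(engine)
  known_outcomes <- c("CLIN_REMISSION", "CPC_REMISSION",
                      "CLIN_RELAPSE_FROM_CPC", "CPC_RELAPSE_FROM_CPC")
  if (!all(outcomes %in% known_outcomes))
    stop("unknown outcome(s): ",
         paste(setdiff(outcomes, known_outcomes), collapse = ", "))
  bad <- setdiff(families, setdiff(.ps_families, "exponential"))
  if (length(bad) > 0)
    stop("unknown family name(s): ", paste(bad, collapse = ", "))
  if (m < 1) stop("m must be at least 1")
  if (lead_in_weeks < 0) stop("lead_in_weeks must be non-negative")
  if (horizon_months <= 0) stop("horizon_months must be positive")
  structure(list(outdir = outdir, cohort = cohort, m = m,
                 outcomes = outcomes, families = families,
                 location = location, shape = shape,
                 lead_in_weeks = lead_in_weeks,
                 horizon_months = horizon_months, engine = engine,
                 n_sim = n_sim, report_months = report_months,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] may be given in a YAML file;
#' formulas as strings (`location: "~ arm + age"`); the cohort as a
#' directory path or omitted for the default generator.
#'
#' @param path YAML file.
#' @param outdir overrides the file's `outdir` if given.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("outdir", "m", "outcomes", "families", "lead_in_weeks",
               "horizon_months", "engine", "n_sim", "report_months",
               "seed", "cohort"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  for (nm in c("location", "shape"))
    if (!is.null(y[[nm]])) args[[nm]] <- stats::as.formula(y[[nm]])
  if (!is.null(outdir)) args$outdir <- outdir
  do.call(pipeline_config, args)
}

.stage <- function(name, log, expr) {
  t0 <- Sys.time()
  message("[", name, "] started")
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  message("[", name, "] done in ", round(el, 1), " s")
  assign(name, el, envir = log)
  res
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the stages in order (cohort, pool, impute, events, km, fit,
#' extrapolate, report), writing every artifact plus a manifest (config
#' echo, seeds, per-stage timings, output checksums) into the run
#' directory. Two runs with the same configuration and seed produce
#' identical outputs. A stage failure halts the run with the stage name;
#' artifacts of completed stages persist, and intermediate state is saved
#' so that later stages can be re-run with `stages = ...` against the same
#' directory.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (default all, in order).
#' @return the run directory, invisibly; the manifest is
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config,
                         stages = c("cohort", "pool", "impute", "events",
                                    "km", "fit", "extrapolate", "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- new.env()
  state_file <- file.path(out, "state.rds")
  st <- if (file.exists(state_file)) readRDS(state_file) else list()

  if ("cohort" %in% stages) {
    st$cohort <- .stage("cohort", log, {
      co <- if (is.character(config$cohort)) read_cohort(config$cohort)
      else {
        cc <- config$cohort
        cc$seed <- child_seed(config$seed, 1L)
        cc$lead_in_weeks <- config$lead_in_weeks
        generate_cohort(cc)
      }
      write_cohort(co, file.path(out, "cohort"))
      co
    })
  }
  if ("pool" %in% stages) {
    st$pooled <- .stage("pool", log, {
      ps <- apply_exclusions(st$cohort)
      utils::write.csv(ps$retention, file.path(out, "retention.csv"),
                       row.names = FALSE)
      utils::write.csv(ps$cohort$baseline,
                       file.path(out, "pooled_baseline.csv"),
                       row.names = FALSE)
      ps
    })
  }
  if ("impute" %in% stages) {
    st$imputed <- .stage("impute", log, {
      im <- fit_imputation_model(st$pooled$cohort)
      res <- impute_missing(im, st$pooled$cohort, m = config$m,
                            seed = child_seed(config$seed, 2L))
      jsonlite::write_json(
        lapply(res$diagnostics, function(d)
          d[c("n_missing", "frac_missing", "between_imputation_sd")]),
        file.path(out, "imputation_diagnostics.json"),
        auto_unbox = TRUE, digits = NA)
      res
    })
  }
  if ("events" %in% stages) {
    st$events <- .stage("events", log, {
      ev <- lapply(seq_len(config$m), function(j)
        derive_events(st$imputed$completed[[j]]))
      flat <- do.call(rbind, lapply(seq_along(ev), function(j)
        cbind(imputation_index = j, ev[[j]])))
      utils::write.csv(flat, file.path(out, "survival_samples.csv"),
                       row.names = FALSE)
      ev
    })
  }
  if ("km" %in% stages) {
    st$km <- .stage("km", log, {
      ev1 <- st$events[[1]]
      res <- lapply(config$outcomes, function(oc) {
        s <- ev1[ev1$outcome == oc, ]
        a <- s[s$arm == "DVS", ]; b <- s[s$arm != "DVS", ]
        km_a <- if (nrow(a) > 0) km_estimate(a) else NULL
        km_b <- if (nrow(b) > 0) km_estimate(b) else NULL
        tests <- if (nrow(a) > 0 && nrow(b) > 0) list(
          logrank = unclass(two_sample_test(a, b, "logrank")),
          peto = unclass(two_sample_test(a, b, "peto"))) else NULL
        list(outcome = oc,
             median_dvs = if (!is.null(km_a)) km_a$median else NA,
             median_soc = if (!is.null(km_b)) km_b$median else NA,
             rmst_dvs = if (!is.null(km_a)) km_a$rmst[["value"]] else NA,
             rmst_soc = if (!is.null(km_b)) km_b$rmst[["value"]] else NA,
             tests = tests)
      })
      names(res) <- config$outcomes
      jsonlite::write_json(res, file.path(out, "km_results.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      res
    })
  }
  if ("fit" %in% stages) {
    st$fits <- .stage("fit", log, {
      fml <- stats::as.formula(
        paste("survival::Surv(time, event) ~",
              paste(deparse(config$location[[2]]), collapse = "")))
      fits <- list(); sel <- list()
      for (oc in config$outcomes) {
        li <- if (grepl("REMISSION", oc)) config$lead_in_weeks else 0
        per_fam <- list()
        for (fam in config$families) {
          ffits <- lapply(seq_len(config$m), function(j) {
            s <- st$events[[j]]
            s <- s[s$outcome == oc, ]
            psfit(fml, data = s, shape = config$shape, family = fam,
                  lead_in = li)
          })
          per_fam[[fam]] <- ffits
        }
        mean_aic <- vapply(per_fam, function(ff)
          mean(vapply(ff, function(f) f$aic %||% Inf, 0)), 0)
        mean_bic <- vapply(per_fam, function(ff)
          mean(vapply(ff, function(f) f$bic %||% Inf, 0)), 0)
        sel[[oc]] <- data.frame(family = names(per_fam),
                                aic = mean_aic, bic = mean_bic,
                                row.names = NULL)
        sel[[oc]] <- sel[[oc]][order(sel[[oc]]$aic), ]
        fits[[oc]] <- per_fam
      }
      for (oc in names(sel))
        utils::write.csv(sel[[oc]],
                         file.path(out, paste0("model_selection_",
                                               tolower(oc), ".csv")),
                         row.names = FALSE)
      fit_summ <- lapply(names(fits), function(oc) {
        lapply(names(fits[[oc]]), function(fam) {
          est <- do.call(rbind, lapply(fits[[oc]][[fam]], stats::coef))
          va <- do.call(rbind, lapply(fits[[oc]][[fam]], function(f)
            diag(f$vcov)))
          pooled <- rubin_pool(est, va)
          list(outcome = oc, family = fam,
               coefficients = stats::setNames(pooled$estimate, pooled$term),
               se = stats::setNames(pooled$se, pooled$term),
               loglik = mean(vapply(fits[[oc]][[fam]],
                                    function(f) f$loglik, 0)),
               aic = mean(vapply(fits[[oc]][[fam]], function(f) f$aic, 0)),
               bic = mean(vapply(fits[[oc]][[fam]], function(f) f$bic, 0)),
               lead_in = fits[[oc]][[fam]][[1]]$lead_in)
        })
      })
      jsonlite::write_json(fit_summ, file.path(out, "fits.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      list(fits = fits, selection = sel)
    })
  }
  if ("extrapolate" %in% stages) {
    st$traces <- .stage("extrapolate", log, {
      sel <- st$fits$selection
      best_rem <- sel$CPC_REMISSION$family[1]
      best_rel <- sel$CPC_RELAPSE_FROM_CPC$family[1]
      pop <- st$imputed$completed[[1]]$baseline
      traces <- list()
      for (armv in c("DVS", "SOC")) {
        tabl <- pop
        tabl$arm <- armv
        tm <- transition_model(
          to_remission = st$fits$fits$CPC_REMISSION[[best_rem]][[1]],
          to_relapse = st$fits$fits$CPC_RELAPSE_FROM_CPC[[best_rel]][[1]],
          covariate_table = tabl, arm = armv,
          lead_in_weeks = config$lead_in_weeks)
        traces[[armv]] <- if (config$engine == "renewal")
          solve_renewal(tm, config$horizon_months)
        else simulate_cohort(tm, n_sim = config$n_sim,
                             horizon_months = config$horizon_months,
                             seed = child_seed(config$seed, 3L))
      }
      for (armv in names(traces))
        utils::write.csv(traces[[armv]]$trace,
                         file.path(out, paste0("trace_", tolower(armv),
                                               ".csv")),
                         row.names = FALSE)
      traces
    })
  }
  if ("report" %in% stages) {
    .stage("report", log, {
      rep <- remission_table(st$traces, config$report_months)
      utils::write.csv(rep, file.path(out, "remission_report.csv"),
                       row.names = FALSE)
      jsonlite::write_json(rep, file.path(out, "remission_report.json"),
                           auto_unbox = TRUE, digits = NA)
      rep
    })
  }
  saveRDS(st, state_file)

  files <- setdiff(list.files(out, recursive = TRUE),
                   c("manifest.json", "state.rds"))
  md5 <- tools::md5sum(file.path(out, files))
  names(md5) <- files
  manifest <- list(
    package = "remex",
    package_version = as.character(utils::packageVersion("remex")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    engine = config$engine,
    m = config$m,
    outcomes = config$outcomes,
    families = config$families,
    lead_in_weeks = config$lead_in_weeks,
    horizon_months = config$horizon_months,
    stage_seconds = as.list(as.list(log)),
    outputs = as.list(md5))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
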