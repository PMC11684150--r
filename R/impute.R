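## Dirichlet draw via gamma variates
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha
  g / sum(g)
}

.visit_vars <- c("pdai_pain", "pdai_discharge")
.nonneg_vars <- c("weight", "cd_duration", "cdai", "age", "n_io", "n_eo")

#' Fit the hierarchical imputation model
#'
#' Builds the per-variable posterior machinery used by [impute_missing()]:
#' \itemize{
#' \item categorical baseline variables get a multinomial model whose
#'   per-study category probabilities are partially pooled towards the
#'   pooled distribution through a Dirichlet prior (`prior_strength`
#'   pseudo-counts distributed as the pooled proportions). During fitting
#'   the category space is extended by an explicit dummy "missing-pattern"
#'   category so that the missingness pattern itself is represented;
#'   imputation draws are taken from the conditional distribution over the
#'   real categories.
#' \item the visit-level PDAI pain and discharge scores are modelled as a
#'   joint (pain, discharge) pair — the two elements are strongly
#'   dependent — within study-by-closure-state strata, the closure
#'   assessment being the shared covariate that carries the disease state.
#'   When one element of a pair is observed, the other is drawn from its
#'   conditional distribution given the observed element.
#' \item numeric variables get a normal regression on shared predictors
#'   with a study-level intercept, fitted on the observed rows; posterior
#'   draws use the asymptotic coefficient distribution and a scaled
#'   inverse-chi-square residual variance. Non-negative scores are
#'   truncated at zero.
#' }
#' A variable observed in no study at all cannot be imputed and is an
#' error; a variable observed in only one study falls back to the pooled
#' distribution for the empty study.
#'
#' @param cohort a `"cpf_cohort"`.
#' @param targets character vector of variables to impute; defaults to
#'   every baseline covariate with missing values plus the visit-level
#'   PDAI scores if they have missing values.
#' @param predictors numeric-model predictors (complete columns; rows with
#'   a missing predictor fall back to its study mean).
#' @param prior_strength Dirichlet pooling weight in pseudo-counts.
#' @return an object of class `"imp_model"`.
#' @export
fit_imputation_model <- function(cohort, targets = NULL,
                                 predictors = "age",
                                 prior_strength = 10) {
  bl <- cohort$baseline; vis <- cohort$visits
  if (is.null(targets)) {
    cand <- setdiff(names(bl),
                    c("patient_id", "study", "arm", "censor_week",
                      "censor_reason", "has_post_index_assessment"))
    cand <- cand[!startsWith(cand, "latent_")]
    targets <- cand[vapply(cand, function(v) anyNA(bl[[v]]), TRUE)]
    for (v in .visit_vars) if (anyNA(vis[[v]])) targets <- c(targets, v)
  }
  studies <- sort(unique(bl$study))
  models <- list()
  ## both PDAI elements targeted: model the (pain, discharge) pair jointly,
  ## since the two scores are strongly dependent within a visit
  if (all(.visit_vars %in% targets)) {
    pick <- vis$week > 0
    strat <- paste(bl$study[match(vis$patient_id[pick], bl$patient_id)],
                   ifelse(is.na(vis$eo_all_closed[pick]), "unk",
                          vis$eo_all_closed[pick]), sep = ".")
    pair <- ifelse(is.na(vis$pdai_pain[pick]) |
                     is.na(vis$pdai_discharge[pick]), NA,
                   vis$pdai_pain[pick] * 4 + vis$pdai_discharge[pick])
    if (all(is.na(pair)))
      stop("variable entirely missing in all studies: pdai scores")
    lev <- 0:15
    strata <- sort(unique(strat))
    tabs <- lapply(strata, function(s) {
      x <- pair[strat == s]
      c(as.numeric(table(factor(x, levels = lev), useNA = "no")),
        sum(is.na(x)))
    })
    names(tabs) <- strata
    pooled_real <- Reduce(`+`, tabs)[seq_along(lev)]
    pp <- (pooled_real + 0.5) / sum(pooled_real + 0.5 * length(lev))
    alpha <- lapply(strata, function(s)
      tabs[[s]][seq_along(lev)] + prior_strength * pp)
    names(alpha) <- strata
    models[["pdai_pair"]] <- list(type = "pdai_pair", levels = lev,
                                  strata = strata, alpha = alpha,
                                  pooled = pp, counts = tabs,
                                  visit = TRUE)
    targets <- setdiff(targets, .visit_vars)
  }
  for (v in targets) {
    is_visit <- v %in% .visit_vars
    if (!is_visit && !v %in% names(bl))
      stop("unknown imputation target: ", v)
    if (is_visit) {
      pick <- vis$week > 0
      val <- vis[[v]][pick]
      ## PDAI categories are modelled within study x closure-state strata:
      ## the closure assessment is the shared covariate that carries the
      ## disease state, and scores differ radically between open and
      ## closed fistulas
      stdy <- paste(bl$study[match(vis$patient_id[pick], bl$patient_id)],
                    ifelse(is.na(vis$eo_all_closed[pick]), "unk",
                           vis$eo_all_closed[pick]), sep = ".")
    } else {
      val <- bl[[v]]
      stdy <- bl$study
    }
    if (all(is.na(val)))
      stop("variable entirely missing in all studies: ", v)
    categorical <- is_visit || !is.numeric(val) ||
      length(unique(val[!is.na(val)])) <= 6
    if (categorical) {
      lev <- if (is.factor(val)) levels(val) else
        sort(unique(val[!is.na(val)]))
      strata <- sort(unique(stdy))
      ## dummy missing-pattern category enters the fitted table
      tabs <- lapply(strata, function(s) {
        x <- val[stdy == s]
        cnt <- table(factor(x, levels = lev), useNA = "no")
        c(as.numeric(cnt), sum(is.na(x)))
      })
      names(tabs) <- strata
      pooled <- Reduce(`+`, tabs)
      K <- length(lev)
      pooled_real <- pooled[seq_len(K)]
      if (sum(pooled_real) == 0)
        stop("no observed categories for: ", v)
      pp <- pooled_real / sum(pooled_real)
      alpha <- lapply(strata, function(s)
        tabs[[s]][seq_len(K)] + prior_strength * pp)
      names(alpha) <- strata
      models[[v]] <- list(type = "categorical", levels = lev,
                          strata = strata,
                          alpha = alpha, pooled = pp,
                          counts = tabs, visit = is_visit,
                          was_factor = is.factor(val))
    } else {
      preds <- intersect(predictors, names(bl))
      preds <- setdiff(preds, v)
      dat <- bl[, c(v, preds, "study"), drop = FALSE]
      ## study-mean fallback for missing predictors
      for (p in preds) if (anyNA(dat[[p]]) && is.numeric(dat[[p]])) {
        mu_s <- tapply(dat[[p]], dat$study, mean, na.rm = TRUE)
        dat[[p]][is.na(dat[[p]])] <- mu_s[dat$study[is.na(dat[[p]])]]
      }
      dat$study <- factor(dat$study, levels = studies)
      obs <- !is.na(dat[[v]])
      fml <- stats::reformulate(c(preds, if (length(studies) > 1) "study"),
                                response = v)
      fit <- stats::lm(fml, data = dat[obs, , drop = FALSE])
      models[[v]] <- list(type = "numeric",
                          coef = stats::coef(fit),
                          vcov = stats::vcov(fit),
                          sigma = stats::sigma(fit),
                          df = fit$df.residual,
                          preds = preds, visit = FALSE,
                          lower = if (v %in% .nonneg_vars) 0 else -Inf)
    }
  }
  structure(list(targets = names(models), models = models,
                 studies = studies, predictors = predictors),
            class = "imp_model")
}

#' Multiply impute missing values
#'
#' Draws `m` independent completions of the cohort from the fitted
#' hierarchical model's (approximate) posterior: each completion uses a
#' fresh draw of the per-study category probabilities / regression
#' parameters, so imputation is never a deterministic fill-in. Observed
#' values are identical across completions.
#'
#' @param model an `"imp_model"` from [fit_imputation_model()].
#' @param cohort the `"cpf_cohort"` to complete.
#' @param m number of completions (default 20).
#' @param seed integer seed; completions are reproducible given it.
#' @return an object of class `"imputation_result"`: `completed` (list of
#'   `m` cohorts), `m`, `seed` and `diagnostics` (per-variable missing
#'   fractions and the between-completion SD of the variable mean).
#' @export
impute_missing <- function(model, cohort, m = 20, seed = 1L) {
  stopifnot(inherits(model, "imp_model"))
  if (m < 1) stop("m must be at least 1")
  bl <- cohort$baseline; vis <- cohort$visits
  studies <- model$studies
  completed <- with_seed(seed, lapply(seq_len(m), function(j) {
    blj <- bl; visj <- vis
    for (v in model$targets) {
      mv <- model$models[[v]]
      if (mv$type == "pdai_pair") {
        idx <- which(visj$week > 0 & (is.na(visj$pdai_pain) |
                                        is.na(visj$pdai_discharge)))
        if (length(idx) == 0) next
        strat <- paste(bl$study[match(visj$patient_id[idx],
                                      bl$patient_id)],
                       ifelse(is.na(visj$eo_all_closed[idx]), "unk",
                              visj$eo_all_closed[idx]), sep = ".")
        strat[!(strat %in% mv$strata)] <- mv$strata[1]
        pain_of <- mv$levels %/% 4; disch_of <- mv$levels %% 4
        for (s in unique(strat)) {
          si <- which(strat == s)
          pi_s <- .rdirichlet(mv$alpha[[s]])
          rows <- idx[si]
          p_obs <- visj$pdai_pain[rows]; d_obs <- visj$pdai_discharge[rows]
          draw_pairs <- function(rws, w) {
            if (length(rws) == 0 || sum(w) == 0) return(invisible(NULL))
            pr <- sample(mv$levels, length(rws), replace = TRUE,
                         prob = w)
            visj$pdai_pain[rws] <<- pr %/% 4
            visj$pdai_discharge[rws] <<- pr %% 4
          }
          draw_pairs(rows[is.na(p_obs) & is.na(d_obs)], pi_s)
          for (val in 0:3) {
            draw_pairs(rows[!is.na(p_obs) & p_obs == val & is.na(d_obs)],
                       pi_s * (pain_of == val))
            draw_pairs(rows[!is.na(d_obs) & d_obs == val & is.na(p_obs)],
                       pi_s * (disch_of == val))
          }
        }
        next
      }
      if (mv$type == "categorical") {
        if (mv$visit) {
          idx <- which(is.na(visj[[v]]) & visj$week > 0)
          stdy <- paste(bl$study[match(visj$patient_id[idx],
                                       bl$patient_id)],
                        ifelse(is.na(visj$eo_all_closed[idx]), "unk",
                               visj$eo_all_closed[idx]), sep = ".")
        } else {
          idx <- which(is.na(blj[[v]]))
          stdy <- blj$study[idx]
        }
        if (length(idx) == 0) next
        ## a stratum unseen at fit time falls back to the pooled draw
        stdy[!(stdy %in% mv$strata)] <- NA
        fill <- rep(NA_integer_, length(idx))
        for (s in mv$strata) {
          si <- !is.na(stdy) & stdy == s
          if (!any(si)) next
          pi_s <- .rdirichlet(mv$alpha[[s]])
          fill[si] <- sample(seq_along(mv$levels), sum(si),
                             replace = TRUE, prob = pi_s)
        }
        if (anyNA(stdy)) {
          si <- is.na(stdy)
          pi_p <- .rdirichlet(mv$pooled * 50 + 1)
          fill[si] <- sample(seq_along(mv$levels), sum(si),
                             replace = TRUE, prob = pi_p)
        }
        newv <- mv$levels[fill]
        if (mv$visit) {
          visj[[v]][idx] <- as.integer(as.character(newv))
        } else if (mv$was_factor) {
          blj[[v]][idx] <- factor(newv, levels = mv$levels)
        } else blj[[v]][idx] <- if (is.numeric(bl[[v]]))
          as.numeric(newv) else newv
      } else {
        idx <- which(is.na(blj[[v]]))
        if (length(idx) == 0) next
        beta <- MASS::mvrnorm(1, mv$coef, mv$vcov)
        sig <- mv$sigma * sqrt(mv$df / stats::rchisq(1, mv$df))
        dat <- blj[idx, , drop = FALSE]
        for (p in mv$preds) if (anyNA(dat[[p]])) {
          mu_s <- tapply(bl[[p]], bl$study, mean, na.rm = TRUE)
          dat[[p]][is.na(dat[[p]])] <- mu_s[dat$study[is.na(dat[[p]])]]
        }
        dat$study <- factor(dat$study, levels = studies)
        X <- stats::model.matrix(
          stats::reformulate(c(mv$preds,
                               if (length(studies) > 1) "study")), dat)
        mu <- drop(X %*% beta[colnames(X)])
        blj[[v]][idx] <- pmax(mu + stats::rnorm(length(idx), 0, sig),
                              mv$lower)
      }
    }
    structure(list(baseline = blj, visits = visj, config = cohort$config),
              class = "cpf_cohort")
  }))
  diagnostics <- lapply(model$targets, function(v) {
    mv <- model$models[[v]]
    if (mv$type == "pdai_pair") {
      pick <- vis$week > 0
      nmiss <- sum(is.na(vis$pdai_pain[pick]) |
                     is.na(vis$pdai_discharge[pick]))
      ntot <- sum(pick)
      means <- vapply(completed, function(co)
        mean(co$visits$pdai_pain[co$visits$week > 0] +
               co$visits$pdai_discharge[co$visits$week > 0]), 0)
    } else if (mv$visit) {
      nmiss <- sum(is.na(vis[[v]][vis$week > 0]))
      ntot <- sum(vis$week > 0)
      means <- vapply(completed, function(co)
        mean(co$visits[[v]][co$visits$week > 0]), 0)
    } else {
      nmiss <- sum(is.na(bl[[v]]))
      ntot <- nrow(bl)
      means <- vapply(completed, function(co) {
        x <- co$baseline[[v]]
        if (is.numeric(x)) mean(x) else mean(x == x[!is.na(x)][1])
      }, 0)
    }
    list(variable = v, n_missing = nmiss, frac_missing = nmiss / ntot,
         between_imputation_sd = stats::sd(means))
  })
  names(diagnostics) <- model$targets
  structure(list(completed = completed, m = m, seed = seed,
                 diagnostics = diagnostics),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("Multiple imputation:", x$m, "completed data sets\n")
  d <- do.call(rbind, lapply(x$diagnostics, function(g)
    data.frame(variable = g$variable, n_missing = g$n_missing,
               frac_missing = round(g$frac_missing, 3),
               between_sd = signif(g$between_imputation_sd, 3))))
  print(d, row.names = FALSE)
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' @param estimates matrix of coefficient estimates, one row per completed
#'   data set.
#' @param variances matrix of squared standard errors, same shape.
#' @return data frame with the pooled `estimate`, total `se`
#'   (within + (1 + 1/m) between), and the degrees of freedom.
#' @export
rubin_pool <- function(estimates, variances) {
  estimates <- as.matrix(estimates); variances <- as.matrix(variances)
  m <- nrow(estimates)
  qbar <- colMeans(estimates)
  ubar <- colMeans(variances)
  b <- apply(estimates, 2, stats::var)
  if (m == 1) b <- 0 * qbar
  tv <- ubar + (1 + 1 / m) * b
  df <- ifelse(b > 0, (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2, Inf)
  data.frame(term = colnames(estimates) %||%
               paste0("b", seq_along(qbar)),
             estimate = qbar, se = sqrt(tv), df = df,
             row.names = NULL)
}
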