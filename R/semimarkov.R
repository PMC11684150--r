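#' Transition model for the semi-Markov remission engine
#'
#' Pairs a fitted time-to-remission model (chronic symptomatic fistula,
#' CSF, to CPC remission) with a fitted time-to-relapse model (remission
#' back to CSF) and the covariate table of the population to extrapolate.
#' Both components may be `"psfit"` objects or, for oracle/closed-form
#' work, a bare list `list(family =, mu =, anc =)` describing one fixed
#' sojourn distribution. `to_relapse = NULL` encodes a sojourn degenerate
#' at infinity (remission is absorbing).
#'
#' Re-entry sojourns reuse the first-event fitted distributions: the fits
#' describe first events only, but the engine runs a relapsing-remitting
#' alternation, so every CSF (remission) spell draws from the same
#' remission (relapse) distribution with its clock reset at entry. The
#' lead-in, which reflects the one-off absence of recorded events right
#' after treatment, is applied to the first CSF sojourn only unless
#' `lead_in_each = TRUE`.
#'
#' @param to_remission,to_relapse transition components (see above).
#' @param covariate_table data frame of covariate profiles the curves are
#'   averaged over (one row per profile); ignored by bare-list components.
#' @param arm label carried through to traces and reports.
#' @param lead_in_weeks lead-in applied to the (first) CSF sojourn;
#'   defaults to the remission fit's own lead-in.
#' @param lead_in_each apply the lead-in to every CSF sojourn.
#' @param weights optional covariate-table row weights (e.g. from
#'   [bias_adjust()]).
#' @return an object of class `"transition_model"`.
#' @export
transition_model <- function(to_remission, to_relapse = NULL,
                             covariate_table = NULL, arm = "arm",
                             lead_in_weeks = NULL, lead_in_each = FALSE,
                             weights = NULL) {
  if (is.null(lead_in_weeks))
    lead_in_weeks <- if (inherits(to_remission, "psfit"))
      to_remission$lead_in else 0
  if (lead_in_weeks < 0) stop("lead_in_weeks must be non-negative")
  if (is.null(covariate_table))
    covariate_table <- data.frame(row.names = 1)
  structure(list(to_remission = to_remission, to_relapse = to_relapse,
                 covariate_table = covariate_table, arm = arm,
                 lead_in_weeks = lead_in_weeks,
                 lead_in_each = lead_in_each,
                 weights = weights),
            class = "transition_model")
}

## resolve a transition component to per-row (mu, anc) over the table
.tm_params <- function(comp, table) {
  n <- max(nrow(table), 1L)
  if (is.null(comp)) return(NULL)
  if (inherits(comp, "psfit")) {
    pm <- .ps_newdata_params(comp, table)
    list(family = comp$family, mu = pm$mu, anc = pm$anc)
  } else {
    stopifnot(is.list(comp), !is.null(comp$family))
    k <- length(ps_family_info(comp$family)$anc_names)
    anc <- if (k > 0) .anc_mat(comp$anc, n, k) else NULL
    list(family = comp$family, mu = rep_len(comp$mu, n), anc = anc)
  }
}

.tm_draw <- function(par, rows) {
  if (is.null(par)) return(rep(Inf, length(rows)))
  anc <- if (is.null(par$anc)) NULL else par$anc[rows, , drop = FALSE]
  ps_rtime(stats::runif(length(rows)), par$family, par$mu[rows], anc)
}

.tm_cdf <- function(par, t, row) {
  if (is.null(par)) return(rep(0, length(t)))
  anc <- if (is.null(par$anc)) NULL else par$anc[row, , drop = FALSE]
  1 - ps_surv(t, par$family, par$mu[row], anc)
}

.check_gompertz_horizon <- function(par, horizon_weeks) {
  if (!is.null(par) && par$family == "gompertz") {
    a <- max(par$anc[, 1])
    if (a > 0 && a * horizon_weeks > 700)
      stop("Gompertz shape ", signif(a, 3), " overflows the survivor ",
           "function before ", round(horizon_weeks), " weeks; shorten the ",
           "horizon or refit with a smaller positive shape")
  }
  invisible(NULL)
}

#' Microsimulate the semi-Markov cohort
#'
#' Each simulated patient enters in the CSF state at time 0, draws a
#' covariate profile from the model's covariate table, and then alternates
#' CSF and remission sojourns drawn from the transition models with the
#' clock reset at every state entry (semi-Markov). State occupancy is
#' recorded on a monthly grid (weeks = months x 52/12).
#'
#' @param model a [transition_model()].
#' @param n_sim number of simulated patients.
#' @param horizon_months last month of the grid.
#' @param seed integer seed.
#' @return an object of class `"cohort_trace"`: data frame `trace` with
#'   `month`, `prop_remission`, `prop_csf`, `se` (binomial Monte-Carlo SE),
#'   plus `n_sim`, `seed`, `arm`, `mode`.
#' @export
simulate_cohort <- function(model, n_sim = 50000, horizon_months = 48,
                            seed = 1L) {
  stopifnot(inherits(model, "transition_model"), n_sim >= 1,
            horizon_months > 0)
  tab <- model$covariate_table
  p_rem <- .tm_params(model$to_remission, tab)
  p_rel <- .tm_params(model$to_relapse, tab)
  hw <- horizon_months * WEEKS_PER_MONTH
  .check_gompertz_horizon(p_rem, hw)
  .check_gompertz_horizon(p_rel, hw)
  months <- 0:horizon_months
  wk <- months * WEEKS_PER_MONTH
  with_seed(seed, {
    nprof <- max(nrow(tab), 1L)
    wts <- model$weights %||% rep(1, nprof)
    prof <- if (nprof == 1L) rep(1L, n_sim) else
      sample.int(nprof, n_sim, replace = TRUE, prob = wts)
    occ <- numeric(length(wk))
    t0 <- rep(0, n_sim)      # current CSF entry time
    active <- rep(TRUE, n_sim)
    first <- TRUE
    guard <- 0L
    while (any(active) && guard < 500L) {
      guard <- guard + 1L
      idx <- which(active)
      s_csf <- .tm_draw(p_rem, prof[idx])
      if (first && model$lead_in_weeks > 0 && !model$lead_in_each)
        s_csf <- s_csf + model$lead_in_weeks
      if (model$lead_in_each) s_csf <- s_csf + model$lead_in_weeks
      enter <- t0[idx] + s_csf
      s_rem <- .tm_draw(p_rel, prof[idx])
      exit <- enter + s_rem
      for (j in seq_along(wk))
        occ[j] <- occ[j] + sum(enter <= wk[j] & wk[j] < exit)
      t0[idx] <- exit
      active[idx] <- is.finite(exit) & exit < hw
      first <- FALSE
    }
    p <- occ / n_sim
    trace <- data.frame(month = months, prop_remission = p,
                        prop_csf = 1 - p,
                        se = sqrt(pmax(p * (1 - p), 0) / n_sim))
    structure(list(trace = trace, n_sim = n_sim, seed = seed,
                   arm = model$arm, mode = "microsim"),
              class = "cohort_trace")
  })
}

#' Deterministic renewal-equation solver for the semi-Markov cohort
#'
#' Solves the alternating-renewal occupancy equations by discrete
#' convolution on a fine weekly sub-grid, per covariate profile, then
#' averages profiles. Serves as the deterministic counterpart (and
#' numerical oracle) of [simulate_cohort()]; the two agree within
#' Monte-Carlo error, with a discretization bias of order `grid_step`.
#'
#' @param model a [transition_model()].
#' @param horizon_months last month of the grid.
#' @param grid_step convolution step in weeks (must be <= 1).
#' @return a `"cohort_trace"` with `mode = "renewal"` (`se` = 0).
#' @export
solve_renewal <- function(model, horizon_months = 48, grid_step = 0.25) {
  stopifnot(inherits(model, "transition_model"), horizon_months > 0)
  if (grid_step > 1) stop("grid_step must be at most 1 week")
  tab <- model$covariate_table
  p_rem <- .tm_params(model$to_remission, tab)
  p_rel <- .tm_params(model$to_relapse, tab)
  hw <- horizon_months * WEEKS_PER_MONTH
  .check_gompertz_horizon(p_rem, hw)
  .check_gompertz_horizon(p_rel, hw)
  N <- ceiling(hw / grid_step) + 1L
  tg <- (seq_len(N) - 1L) * grid_step
  nprof <- max(nrow(tab), 1L)
  wts <- model$weights %||% rep(1, nprof)
  wts <- wts / sum(wts)
  li <- model$lead_in_weeks
  conv_tr <- function(a, b) {  # truncated open convolution, mass x mass
    out <- stats::convolve(a, rev(b), type = "open")[seq_len(N)]
    pmax(out, 0)
  }
  acc <- numeric(N)
  for (i in seq_len(nprof)) {
    F1 <- .tm_cdf(p_rem, tg, i)
    F1_first <- if (li > 0) {
      ts <- pmax(tg - li, 0)
      .tm_cdf(p_rem, ts, i) * (tg >= li)
    } else F1
    if (model$lead_in_each && li > 0) F1 <- F1_first
    F2 <- .tm_cdf(p_rel, tg, i)
    S2 <- 1 - F2
    p1 <- diff(c(0, F1)); p1f <- diff(c(0, F1_first))
    p2 <- diff(c(0, F2))
    g <- conv_tr(p2, p1)     # full remission->remission cycle
    R <- p1f                 # remission-entry mass per bin
    add <- conv_tr(p1f, g)
    it <- 0L
    while (sum(add) > 1e-12 && it < 500L) {
      it <- it + 1L
      R <- R + add
      add <- conv_tr(add, g)
    }
    ## in remission at t: entered at some s <= t, no relapse since
    P <- stats::convolve(R, rev(S2), type = "open")[seq_len(N)]
    acc <- acc + wts[i] * pmin(pmax(P, 0), 1)
  }
  months <- 0:horizon_months
  idx <- pmin(round(months * WEEKS_PER_MONTH / grid_step) + 1L, N)
  p <- acc[idx]
  p[months == 0] <- 0
  trace <- data.frame(month = months, prop_remission = p,
                      prop_csf = 1 - p, se = 0)
  structure(list(trace = trace, n_sim = NA_integer_, seed = NA_integer_,
                 grid_step = grid_step,
                 arm = model$arm, mode = "renewal"),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Semi-Markov cohort trace (", x$mode, "), arm ", x$arm, "\n", sep = "")
  sel <- x$trace$month %in% c(0, 8, 24, 48) |
    x$trace$month == max(x$trace$month)
  print(x$trace[sel, c("month", "prop_remission")], row.names = FALSE)
  invisible(x)
}

#' Reweight a covariate table to reference moments
#'
#' Entropy-balancing-style adjustment: finds the minimum-relative-entropy
#' weights under which the weighted means of the selected covariates equal
#' the reference table's means. Used to bias-adjust an extrapolation
#' population for differential inclusion between data sources.
#'
#' @param covariate_table data frame to reweight.
#' @param reference_table data frame defining the target means.
#' @param vars covariates to balance (default: all numeric columns shared
#'   by the two tables).
#' @param tol feasibility tolerance on the achieved means.
#' @return an object of class `"weighted_table"`: `table`, `weights`
#'   (normalized to mean 1), `target`, `achieved`.
#' @export
bias_adjust <- function(covariate_table, reference_table, vars = NULL,
                        tol = 1e-6) {
  if (is.null(vars)) {
    shared <- intersect(names(covariate_table), names(reference_table))
    vars <- shared[vapply(shared, function(v)
      is.numeric(covariate_table[[v]]) &&
        is.numeric(reference_table[[v]]), TRUE)]
  }
  if (length(vars) == 0) stop("no covariates to balance")
  X <- as.matrix(covariate_table[, vars, drop = FALSE])
  target <- colMeans(as.matrix(reference_table[, vars, drop = FALSE]))
  Xc <- sweep(X, 2, target)
  scl <- pmax(apply(abs(Xc), 2, max), 1e-12)
  Xs <- sweep(Xc, 2, scl, "/")
  dual <- function(lam) log(mean(exp(drop(Xs %*% lam))))
  grad <- function(lam) {
    w <- exp(drop(Xs %*% lam)); w <- w / sum(w)
    drop(t(Xs) %*% w)
  }
  op <- stats::optim(rep(0, length(vars)), dual, grad, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-14))
  w <- exp(drop(Xs %*% op$par))
  w <- w / mean(w)
  achieved <- colSums(X * w) / sum(w)
  bad <- abs(achieved - target) / pmax(abs(target), 1) > tol
  if (any(bad))
    stop("infeasible moment constraint(s): ",
         paste(vars[bad], collapse = ", "),
         " (target outside the support of the table)")
  structure(list(table = covariate_table, weights = w,
                 target = target, achieved = achieved),
            class = "weighted_table")
}

#' Tabulate the percentage in CPC remission by arm and month
#'
#' @param traces named list of `"cohort_trace"` objects (one per arm) on a
#'   common monthly grid.
#' @param months months to report (default 0, 8, 24, 48).
#' @return data frame with one percentage column per arm and, for two
#'   arms, their difference (percentage points).
#' @export
remission_table <- function(traces, months = c(0, 8, 24, 48)) {
  stopifnot(is.list(traces), length(traces) >= 1, !is.null(names(traces)))
  out <- data.frame(month = months)
  for (nm in names(traces)) {
    tr <- traces[[nm]]$trace
    if (!all(months %in% tr$month))
      stop("requested month beyond the trace horizon: ",
           paste(setdiff(months, tr$month), collapse = ", "))
    out[[nm]] <- 100 * tr$prop_remission[match(months, tr$month)]
  }
  if (length(traces) == 2)
    out$difference <- out[[2]] - out[[3]]
  out
}

#' Plot cohort traces (proportion in remission vs months)
#'
#' @param traces named list of `"cohort_trace"` objects.
#' @param ... passed to [graphics::plot].
#' @export
plot_traces <- function(traces, ...) {
  stopifnot(length(traces) >= 1)
  h <- max(vapply(traces, function(t) max(t$trace$month), 0))
  plot(NULL, xlim = c(0, h), ylim = c(0, 1), xlab = "months",
       ylab = "proportion in CPC remission", ...)
  for (i in seq_along(traces))
    graphics::lines(traces[[i]]$trace$month,
                    traces[[i]]$trace$prop_remission, col = i, lwd = 2)
  graphics::legend("bottomright", names(traces), col = seq_along(traces),
                   lty = 1, bty = "n")
  invisible(traces)
}
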