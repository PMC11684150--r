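#' Log-likelihood of a parametric survival sample
#'
#' Per-observation contribution \eqn{d \log h(t) + \log S(t)} of a
#' right-censored sample under one of the supported families, with the
#' location and ancillary parameters supplied per observation. This is the
#' likelihood kernel maximized by [psfit()].
#'
#' @param time event/censoring times (must be positive; apply any lead-in
#'   shift first, see [apply_lead_in()]).
#' @param event 0/1 censoring indicator.
#' @param family family name, see [ps_families].
#' @param mu per-observation location parameter (recycled).
#' @param anc per-observation ancillary parameters on the natural scale
#'   (vector or matrix, see [ps_families]).
#' @param aggregate if `TRUE` (default) return the summed log-likelihood,
#'   otherwise the vector of per-observation contributions.
#' @return a scalar or vector of log-likelihood contributions.
#' @export
ps_loglik <- function(time, event, family, mu, anc = NULL, aggregate = TRUE) {
  if (any(time <= 0)) stop("ps_loglik requires strictly positive times")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  ll <- ps_logS(time, family, mu, anc)
  ev <- event == 1
  if (any(ev)) {
    n <- length(ll)
    mu <- rep_len(mu, n)
    k <- length(ps_family_info(family)$anc_names)
    a <- .anc_mat(anc, n, k)
    ll[ev] <- ll[ev] + ps_logh(time[ev], family, mu[ev], a[ev, , drop = FALSE])
  }
  bad <- !is.finite(ll)
  if (any(bad))
    stop("non-finite log-likelihood contribution at observation(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  if (aggregate) sum(ll) else ll
}

## map the unconstrained parameter vector to (mu, anc) given design matrices
.ps_param_map <- function(theta, family, X, Z) {
  p <- ncol(X); info <- ps_family_info(family)
  mu <- drop(X %*% theta[seq_len(p)])
  nanc <- length(info$anc_names)
  if (nanc == 0L) return(list(mu = mu, anc = NULL))
  q <- ncol(Z)
  eta <- drop(Z %*% theta[p + seq_len(q)])
  a1 <- if (info$links[1] == "log") exp(eta) else eta
  if (nanc == 1L) return(list(mu = mu, anc = cbind(a1)))
  ## gengamma: second ancillary Q is a scalar on the identity link
  Q <- theta[p + q + 1L]
  list(mu = mu, anc = cbind(a1, rep_len(Q, length(mu))))
}

.ps_nll <- function(theta, family, time, event, X, Z, w) {
  pm <- tryCatch(.ps_param_map(theta, family, X, Z), error = function(e) NULL)
  if (is.null(pm)) return(1e10)
  ll <- tryCatch(
    ps_loglik(time, event, family, pm$mu, pm$anc, aggregate = FALSE),
    error = function(e) NULL)
  if (is.null(ll) || any(!is.finite(ll))) return(1e10)
  -sum(w * ll)
}

## deterministic start values on the scaled design
.ps_starts <- function(family, time, event, p, q) {
  lt <- log(time[event == 1])
  if (length(lt) < 2L) lt <- log(time)
  m0 <- mean(lt); s0 <- max(stats::sd(lt), 0.2)
  rate0 <- log(max(sum(event), 1) / sum(time))
  base <- switch(family,
    exponential = list(c(rate0, rep(0, p - 1))),
    weibull = list(c(m0, rep(0, p - 1), log(1.28 / s0), rep(0, q - 1))),
    llogis  = list(c(m0, rep(0, p - 1), log(1.81 / s0), rep(0, q - 1))),
    lnorm   = list(c(m0, rep(0, p - 1), log(s0), rep(0, q - 1))),
    gompertz = list(c(rate0, rep(0, p - 1), 0, rep(0, q - 1)),
                    c(rate0, rep(0, p - 1), -0.01, rep(0, q - 1))),
    gengamma = list(c(m0, rep(0, p - 1), log(s0), rep(0, q - 1), 0),
                    c(m0, rep(0, p - 1), log(s0), rep(0, q - 1), 1))
  )
  ## one dispersed start guards against shallow local optima
  extra <- lapply(base[1], function(th) { th[1] <- th[1] + 0.7; th })
  c(base, extra)
}

#' Fit a covariate-adjusted parametric survival model
#'
#' Maximum-likelihood fitting of one of five parametric time-to-event
#' families in which both the location parameter (\eqn{\mu = x'\beta}) and
#' the first ancillary (shape) parameter, through its link, are linear
#' functions of covariates. Designed for remission/relapse extrapolation
#' where a lead-in window — an initial period during which events are
#' structurally absent — must be honoured: times are shifted by `lead_in`
#' before entering the likelihood and fitted curves are flat at 1 over it.
#'
#' Optimization is multi-start quasi-Newton (BFGS with a Nelder-Mead
#' fallback) on the unconstrained scale, with covariates internally centred
#' and scaled; the generalized gamma additionally starts from its nested
#' Weibull and log-normal solutions. The reported variance-covariance matrix
#' comes from the numerical Hessian at the optimum.
#'
#' @param formula a formula with a [survival::Surv] response and the
#'   location covariates on the right-hand side.
#' @param data data frame holding the variables.
#' @param shape one-sided formula for the shape linear predictor
#'   (default intercept-only). For the generalized gamma this models
#'   \eqn{\log\sigma}; \eqn{Q} is always a scalar.
#' @param family family name, see [ps_families].
#' @param lead_in lead-in window in weeks (default 0). Event times at or
#'   below the lead-in are flagged (`$leadin_violations`), as they
#'   contradict the premise of the window.
#' @param weights optional non-negative case weights.
#' @param starts optional list of start vectors on the *scaled* parameter
#'   scale, overriding the built-in starts.
#' @return an object of class `"psfit"` with `print`, `summary`, `coef`,
#'   `logLik`, `vcov`, `predict`, `simulate`, `residuals` and `plot`
#'   methods. Key fields: `coefficients`, `loglik`, `aic`, `bic`, `vcov`,
#'   `converged`.
#' @examples
#' d <- data.frame(time = rweibull(80, 1.3, 20), event = 1)
#' f <- psfit(survival::Surv(time, event) ~ 1, d, family = "weibull")
#' summary(f)
#' @export
psfit <- function(formula, data, shape = ~1, family, lead_in = 0,
                  weights = NULL, starts = NULL) {
  family <- ps_check_family(family)
  if (lead_in < 0) stop("lead_in must be non-negative")
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv")) stop("response must be a survival::Surv object")
  time <- as.numeric(y[, 1]); event <- as.numeric(y[, 2])
  if (any(time <= 0)) stop("times must be positive")
  Xt <- stats::delete.response(stats::terms(formula, data = data))
  X <- stats::model.matrix(Xt, mf)
  Zt <- stats::terms(shape, data = data)
  zmf <- stats::model.frame(Zt, data, na.action = stats::na.omit)
  Z <- stats::model.matrix(Zt, zmf)
  if (nrow(Z) != nrow(X))
    stop("shape covariates introduce extra missingness; ",
         "complete cases required")
  w <- if (is.null(weights)) rep(1, nrow(X)) else rep_len(weights, nrow(X))
  if (any(w < 0)) stop("weights must be non-negative")

  viol <- sum(event == 1 & time <= lead_in)
  if (viol > 0)
    warning(viol, " event(s) at or before the lead-in window")
  tfit <- pmax(time - lead_in, 1e-3)

  info <- ps_family_info(family)
  nanc <- length(info$anc_names)
  if (family == "exponential") Z <- Z[, 0, drop = FALSE]
  p <- ncol(X); q <- ncol(Z)
  k <- p + q + as.integer(family == "gengamma")
  nev <- sum(event)
  if (nev < k + 1)
    warning("only ", nev, " events for ", k, " parameters; ",
            "estimates may be unstable")

  ## centre/scale non-intercept columns; exact linear back-transform later
  sc <- function(M) {
    ctr <- rep(0, ncol(M)); scl <- rep(1, ncol(M))
    for (j in seq_len(ncol(M))) {
      v <- M[, j]
      if (stats::sd(v) > 0 && !all(v %in% c(0, 1))) {
        ctr[j] <- mean(v); scl[j] <- stats::sd(v)
        M[, j] <- (v - ctr[j]) / scl[j]
      }
    }
    list(M = M, ctr = ctr, scl = scl)
  }
  sx <- sc(X); sz <- sc(Z)

  if (is.null(starts)) {
    starts <- .ps_starts(family, tfit, event, p, max(q, 1L))
    if (family == "gengamma") {
      ## nested-solution starts tame the generalized gamma's ridge
      for (nest in c("weibull", "lnorm")) {
        nf <- tryCatch(
          psfit_refit(family = nest, time = tfit, event = event,
                      X = sx$M, Z = sz$M, w = w),
          error = function(e) NULL)
        if (!is.null(nf) && nf$converged) {
          th <- nf$theta
          if (nest == "weibull") {
            ## gengamma(mu, sigma = 1/shape, Q = 1) == weibull(shape, e^mu)
            shp <- exp(th[p + 1])
            starts <- c(starts, list(c(th[seq_len(p)], -th[p + 1],
                                       rep(0, q - 1), 1)))
            rm(shp)
          } else {
            starts <- c(starts, list(c(th[seq_len(p)], th[p + 1],
                                       rep(0, q - 1), 0)))
          }
        }
      }
    }
  }

  best <- NULL
  for (th0 in starts) {
    if (length(th0) != k) next
    op <- tryCatch(
      stats::optim(th0, .ps_nll, family = family, time = tfit, event = event,
                   X = sx$M, Z = sz$M, w = w, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(op))
      op <- tryCatch(
        stats::optim(th0, .ps_nll, family = family, time = tfit,
                     event = event, X = sx$M, Z = sz$M, w = w,
                     method = "Nelder-Mead",
                     control = list(maxit = 2000)),
        error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) {
    out <- list(call = cl, family = family, converged = FALSE,
                failure = "all starts failed")
    class(out) <- "psfit"
    return(out)
  }
  ## polish + Hessian at the optimum
  op <- tryCatch(
    stats::optim(best$par, .ps_nll, family = family, time = tfit,
                 event = event, X = sx$M, Z = sz$M, w = w, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12), hessian = TRUE),
    error = function(e) NULL)
  if (!is.null(op) && op$value <= best$value + 1e-8) best <- op
  converged <- !is.null(best$convergence) && best$convergence == 0 &&
    best$value < 1e9

  ## back-transform to the original covariate scale:
  ## beta_j = betaS_j / s_j, beta_0 = betaS_0 - sum betaS_j c_j / s_j
  Tm <- diag(k)
  backblock <- function(Tm, off, ctr, scl, nc) {
    for (j in seq_len(nc)) {
      if (scl[j] != 1) Tm[off + j, off + j] <- 1 / scl[j]
      if (ctr[j] != 0) Tm[off + 1, off + j] <- -ctr[j] / scl[j]
    }
    Tm
  }
  Tm <- backblock(Tm, 0L, sx$ctr, sx$scl, p)
  if (q > 0) Tm <- backblock(Tm, p, sz$ctr, sz$scl, q)
  theta <- drop(Tm %*% best$par)
  V <- matrix(NA_real_, k, k)
  if (!is.null(best$hessian)) {
    Vs <- tryCatch(solve(best$hessian), error = function(e) NULL)
    if (!is.null(Vs)) V <- Tm %*% Vs %*% t(Tm)
  }

  nm <- c(colnames(X),
          if (q > 0) paste0("shape(", colnames(Z), ")"),
          if (family == "gengamma") "Q")
  names(theta) <- nm; dimnames(V) <- list(nm, nm)
  ll <- -best$value
  n <- length(time)
  out <- list(
    call = cl, family = family, coefficients = theta,
    np_location = p, np_shape = q,
    loglik = ll, n = n, nevent = nev, k = k,
    aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
    vcov = V, converged = converged, lead_in = lead_in,
    leadin_violations = viol,
    theta_scaled = best$par,
    loc_terms = Xt, shape_terms = Zt,
    xlevels = stats::.getXlevels(Xt, mf),
    zlevels = stats::.getXlevels(Zt, zmf),
    time = time, event = event, weights = w,
    data_fingerprint = c(n = n, d = nev, tsum = sum(time)))
  class(out) <- "psfit"
  out
}

## bare-metal refit used for gengamma nested starts (scaled design in, no
## back-transform)
psfit_refit <- function(family, time, event, X, Z, w) {
  p <- ncol(X); q <- ncol(Z)
  starts <- .ps_starts(family, time, event, p, max(q, 1L))
  best <- NULL
  for (th0 in starts) {
    op <- tryCatch(
      stats::optim(th0, .ps_nll, family = family, time = time, event = event,
                   X = X, Z = Z, w = w, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) return(list(converged = FALSE))
  list(theta = best$par, converged = best$convergence == 0)
}

## resolve (mu, anc) for new data rows
.ps_newdata_params <- function(object, newdata) {
  if (is.null(newdata)) stop("newdata with the model covariates is required")
  need <- union(all.vars(object$loc_terms), all.vars(object$shape_terms))
  absent <- setdiff(need, names(newdata))
  if (length(absent) > 0)
    stop("newdata is missing model covariate(s): ",
         paste(absent, collapse = ", "))
  mfX <- stats::model.frame(object$loc_terms, newdata,
                            xlev = object$xlevels, na.action = stats::na.fail)
  X <- stats::model.matrix(object$loc_terms, mfX)
  Z <- stats::model.matrix(object$shape_terms,
                           stats::model.frame(object$shape_terms, newdata,
                                              xlev = object$zlevels,
                                              na.action = stats::na.fail))
  if (object$family == "exponential") Z <- Z[, 0, drop = FALSE]
  if (ncol(X) != object$np_location || ncol(Z) != object$np_shape)
    stop("newdata does not provide every model covariate")
  .ps_param_map(object$coefficients, object$family, X, Z)
}

#' Predict survival or hazard curves from a fitted model
#'
#' Evaluates the fitted survival (or hazard) curve at the requested times for
#' each covariate profile in `newdata`, honouring the lead-in plateau
#' (S = 1, h = 0 before the lead-in ends). With `average = TRUE` a single
#' population-averaged curve — the (weighted) mean of the per-row survival
#' curves — is returned, which is how population-adjusted effectiveness
#' curves are produced from a covariate table.
#'
#' @param object a `"psfit"` object.
#' @param newdata data frame of covariate profiles (one row per profile).
#' @param times evaluation times in weeks (default: weekly grid to the
#'   largest observed time).
#' @param type `"survival"` or `"hazard"`.
#' @param average average the per-row curves into one population curve.
#' @param weights optional per-row averaging weights.
#' @param ... unused.
#' @return a data frame with column `time` and either one column per profile
#'   (`S1`, `S2`, ...) or a single `value` column when `average = TRUE`.
#' @export
predict.psfit <- function(object, newdata = NULL,
                          times = NULL, type = c("survival", "hazard"),
                          average = FALSE, weights = NULL, ...) {
  type <- match.arg(type)
  if (!isTRUE(object$converged) && is.null(object$coefficients))
    stop("model did not converge; no coefficients available")
  if (is.null(times)) times <- seq(0, max(object$time), by = 1)
  if (is.null(newdata)) newdata <- data.frame(row.names = 1)
  pm <- .ps_newdata_params(object, newdata)
  li <- object$lead_in
  ts <- pmax(times - li, 0)
  nr <- length(pm$mu)
  out <- matrix(NA_real_, length(times), nr)
  for (i in seq_len(nr)) {
    anc_i <- if (is.null(pm$anc)) NULL else pm$anc[i, , drop = FALSE]
    if (type == "survival") {
      out[, i] <- ps_surv(ts, object$family, pm$mu[i], anc_i)
      out[times < li, i] <- 1
    } else {
      v <- numeric(length(times))
      pos <- ts > 0
      v[pos] <- ps_haz(ts[pos], object$family, pm$mu[i], anc_i)
      out[, i] <- v
    }
  }
  if (average) {
    wts <- if (is.null(weights)) rep(1, nr) else rep_len(weights, nr)
    wts <- wts / sum(wts)
    return(data.frame(time = times, value = drop(out %*% wts)))
  }
  res <- data.frame(time = times)
  colnames(out) <- paste0("S", seq_len(nr))
  cbind(res, out)
}

#' Simulate event times from a fitted model
#'
#' Inverse-survival sampling of event times for each row of `newdata`,
#' shifted by the model's lead-in. Used both for parametric bootstrap checks
#' and as the sojourn sampler of the semi-Markov engine.
#'
#' @param object a `"psfit"` object.
#' @param nsim draws per covariate row.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @param newdata covariate profiles; defaults to a single intercept-only row.
#' @param ... unused.
#' @return a matrix with `nrow(newdata)` rows and `nsim` columns of times in
#'   weeks (possibly `Inf` under defective distributions).
#' @export
simulate.psfit <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                           ...) {
  if (is.null(newdata)) newdata <- data.frame(row.names = 1)
  pm <- .ps_newdata_params(object, newdata)
  nr <- length(pm$mu)
  sim <- function() {
    u <- matrix(stats::runif(nr * nsim), nr, nsim)
    t <- matrix(NA_real_, nr, nsim)
    for (j in seq_len(nsim)) {
      t[, j] <- object$lead_in +
        ps_rtime(u[, j], object$family, pm$mu, pm$anc)
    }
    t
  }
  if (is.null(seed)) sim() else with_seed(seed, sim())
}

#' @export
print.psfit <- function(x, digits = 4, ...) {
  cat("Parametric survival fit (", x$family, ")\n", sep = "")
  if (!isTRUE(x$converged)) cat("  ** did not converge **\n")
  if (is.null(x$coefficients)) return(invisible(x))
  cat("  n =", x$n, " events =", x$nevent,
      " lead-in =", x$lead_in, "weeks\n")
  cat("  logLik =", format(x$loglik, digits = digits),
      " AIC =", format(x$aic, digits = digits),
      " BIC =", format(x$bic, digits = digits), "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.psfit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               z = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coef_table = tab)
  class(out) <- "summary.psfit"
  out
}

#' @export
print.summary.psfit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\n")
  stats::printCoefmat(x$coef_table, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.psfit <- function(object, ...) object$coefficients

#' @export
vcov.psfit <- function(object, ...) object$vcov

#' @export
logLik.psfit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Cox-Snell residuals
#'
#' The fitted cumulative hazard at each observed (lead-in shifted) time;
#' under a well-specified model these behave like a censored unit-exponential
#' sample.
#'
#' @param object a `"psfit"` object.
#' @param newdata the data used for fitting (needed to rebuild the design
#'   matrices); defaults to an intercept-only design if the model has no
#'   covariates.
#' @param ... unused.
#' @return numeric vector of residuals.
#' @export
residuals.psfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata) &&
      (object$np_location > 1 || object$np_shape > 1))
    stop("covariate models need `newdata` (the fitting data)")
  if (is.null(newdata))
    newdata <- data.frame(row.names = seq_along(object$time))
  pm <- .ps_newdata_params(object, newdata)
  ts <- pmax(object$time - object$lead_in, 1e-3)
  -ps_logS(ts, object$family, pm$mu, pm$anc)
}

#' Plot a fitted parametric curve over the Kaplan-Meier estimate
#'
#' Goodness-of-fit display: the non-parametric KM curve of the fitting data
#' with the fitted (population-averaged, if covariates are present) survival
#' curve overlaid.
#'
#' @param x a `"psfit"` object.
#' @param newdata covariate table for averaging (the fitting data).
#' @param horizon largest time to draw, weeks.
#' @param ... passed to [graphics::plot].
#' @export
plot.psfit <- function(x, newdata = NULL, horizon = NULL, ...) {
  km <- survival::survfit(survival::Surv(x$time, x$event) ~ 1)
  if (is.null(horizon)) horizon <- max(x$time)
  if (is.null(newdata))
    newdata <- data.frame(row.names = seq_along(x$time))
  pc <- predict(x, newdata, times = seq(0, horizon, length.out = 200),
                average = TRUE)
  plot(km, conf.int = FALSE, xlab = "weeks", ylab = "S(t)",
       xlim = c(0, horizon), ...)
  graphics::lines(pc$time, pc$value, col = 2, lwd = 2)
  graphics::legend("topright", c("Kaplan-Meier", paste0("fitted ", x$family)),
                   lty = 1, col = c(1, 2), bty = "n")
  invisible(x)
}

#' Compare fitted models by information criteria
#'
#' Ranks a set of fits of *the same data* by AIC, reporting BIC and
#' AIC differences from the best model. Fits on different datasets are
#' refused.
#'
#' @param ... `"psfit"` objects, or a single list of them.
#' @return a data frame sorted by AIC with columns `family`, `k`, `loglik`,
#'   `aic`, `bic`, `delta_aic`, `converged`; class `"ps_comparison"`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "psfit"))
    fits <- fits[[1]]
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "psfit")))
  fp <- vapply(fits, function(f) f$data_fingerprint, numeric(3))
  if (any(apply(fp, 1, function(v) max(abs(v - v[1]))) > 1e-8))
    stop("fits are not all on the same samples")
  tab <- data.frame(
    family = vapply(fits, function(f) f$family, ""),
    k = vapply(fits, function(f) f$k, 0L),
    loglik = vapply(fits, function(f) f$loglik, 0),
    aic = vapply(fits, function(f) f$aic, 0),
    bic = vapply(fits, function(f) f$bic, 0),
    converged = vapply(fits, function(f) isTRUE(f$converged), TRUE))
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  class(tab) <- c("ps_comparison", "data.frame")
  tab
}
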