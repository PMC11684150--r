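#' Kaplan-Meier estimate with Greenwood variance, median and RMST
#'
#' Product-limit estimate of a survival-sample set (events precede
#' censorings at tied times, the standard convention). The median is the
#' first time at which the estimate drops to 0.5 or below (`NA` if never
#' reached), with a log-log (Brookmeyer-Crowley-style) 95% CI. The
#' restricted mean survival time (RMST) is the area under the curve up to
#' the horizon `tau`, which defaults to the largest observed time.
#'
#' @param samples data frame with `time` and `event` columns (0/1), e.g.
#'   from [derive_remission()].
#' @param tau RMST horizon in weeks.
#' @param conf.level confidence level for median and RMST intervals.
#' @return an object of class `"km_fit"`: `time`, `surv`, `n_risk`,
#'   `n_event`, `greenwood_se` (SE of S by Greenwood's formula), `median`
#'   (+ CI), `rmst` (value, `tau`, CI), and the underlying
#'   [survival::survfit] object in `$fit`.
#' @export
km_estimate <- function(samples, tau = NULL, conf.level = 0.95) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1,
            all(c("time", "event") %in% names(samples)))
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1, data = samples,
    conf.type = "log-log", conf.int = conf.level)
  if (is.null(tau)) tau <- max(samples$time)
  tab <- summary(fit, rmean = tau)$table
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  med <- unname(tab["median"])
  rmean <- unname(tab["rmean"]); rse <- unname(tab["se(rmean)"])
  out <- list(
    time = fit$time, surv = fit$surv,
    n_risk = fit$n.risk, n_event = fit$n.event,
    greenwood_se = fit$surv * fit$std.err,
    median = med,
    median_ci = c(lower = unname(tab["0.95LCL"]),
                  upper = unname(tab["0.95UCL"])),
    rmst = c(value = rmean, tau = tau,
             lower = rmean - z * rse, upper = rmean + z * rse),
    n = nrow(samples), nevent = sum(samples$event),
    conf.level = conf.level, fit = fit)
  class(out) <- "km_fit"
  out
}

#' @export
print.km_fit <- function(x, digits = 4, ...) {
  cat("Kaplan-Meier estimate: n =", x$n, " events =", x$nevent, "\n")
  cat("  median =", format(x$median, digits = digits),
      " (", format(x$median_ci[1], digits = digits), ",",
      format(x$median_ci[2], digits = digits), ")\n")
  cat("  RMST(tau =", format(x$rmst[["tau"]], digits = digits), ") =",
      format(x$rmst[["value"]], digits = digits), "\n")
  invisible(x)
}

#' @export
plot.km_fit <- function(x, ...) {
  plot(x$fit, xlab = "weeks", ylab = "S(t)", ...)
  invisible(x)
}

#' Two-sample survival tests
#'
#' Log-rank (Mantel-Haenszel) and Gehan-Wilcoxon tests of equality of two
#' survival curves; the Wilcoxon variant uses Peto & Peto weights (the
#' left-continuous pooled KM estimate), which are non-increasing in time
#' and down-weight late risk sets. Both give a 1-df chi-square statistic.
#' If neither group has any event the statistic is 0 with p = 1.
#'
#' @param samples_a,samples_b data frames with `time` and `event`.
#' @param method `"logrank"` or `"peto"` (Gehan-Wilcoxon with the
#'   Peto-Peto approximation).
#' @return an object of class `"surv_test"`: `method`, `statistic`, `df`,
#'   `p_value`.
#' @export
two_sample_test <- function(samples_a, samples_b,
                            method = c("logrank", "peto")) {
  method <- match.arg(method)
  stopifnot(nrow(samples_a) >= 1, nrow(samples_b) >= 1)
  d <- rbind(
    data.frame(time = samples_a$time, event = samples_a$event, g = "A"),
    data.frame(time = samples_b$time, event = samples_b$event, g = "B"))
  rho <- if (method == "logrank") 0 else 1
  sd <- tryCatch(
    suppressWarnings(
      survival::survdiff(survival::Surv(time, event) ~ g, data = d,
                         rho = rho)),
    error = function(e) NULL)
  if (is.null(sd) || sum(d$event) == 0 || !is.finite(sd$chisq)) {
    stat <- 0; p <- 1
  } else {
    stat <- unname(sd$chisq)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  out <- list(method = if (method == "logrank") "LOGRANK" else
                "GEHAN_WILCOXON_PETO",
              statistic = stat, df = 1L, p_value = p)
  class(out) <- "surv_test"
  out
}

#' @export
print.surv_test <- function(x, digits = 4, ...) {
  cat(x$method, ": chi-square =", format(x$statistic, digits = digits),
      "on", x$df, "df, p =", format(x$p_value, digits = digits), "\n")
  invisible(x)
}

#' Overlayed Kaplan-Meier display for two arms
#'
#' @param samples_by_arm named list of survival-sample data frames.
#' @param ... passed to [graphics::plot].
#' @export
plot_km_arms <- function(samples_by_arm, ...) {
  stopifnot(is.list(samples_by_arm), length(samples_by_arm) >= 1)
  d <- do.call(rbind, lapply(names(samples_by_arm), function(nm)
    data.frame(time = samples_by_arm[[nm]]$time,
               event = samples_by_arm[[nm]]$event, arm = nm)))
  fit <- survival::survfit(survival::Surv(time, event) ~ arm, data = d)
  plot(fit, col = seq_along(samples_by_arm), xlab = "weeks", ylab = "S(t)",
       ...)
  graphics::legend("topright", names(samples_by_arm),
                   col = seq_along(samples_by_arm), lty = 1, bty = "n")
  invisible(fit)
}
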