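#' Parametric survival families
#'
#' The five families used for remission/relapse extrapolation, in the
#' parameterizations that make published formulae unambiguous:
#' \describe{
#'   \item{weibull}{\eqn{S(t) = \exp\{-(t/e^\mu)^s\}} with shape \eqn{s > 0}
#'     (log link).}
#'   \item{gompertz}{hazard \eqn{h(t) = e^\mu e^{at}} with rate \eqn{e^\mu}
#'     and shape \eqn{a} on the identity link (\eqn{a} may be negative;
#'     \eqn{a \to 0} recovers the exponential).}
#'   \item{gengamma}{generalized gamma in the (\eqn{\mu}, \eqn{\sigma},
#'     \eqn{Q}) form, nesting the Weibull at \eqn{Q = 1} and the log-normal
#'     at \eqn{Q = 0}.}
#'   \item{llogis}{\eqn{S(t) = 1/\{1 + (t/e^\mu)^s\}}, shape on the log link.}
#'   \item{lnorm}{\eqn{S(t) = 1 - \Phi\{(\log t - \mu)/\sigma\}}, \eqn{\sigma}
#'     on the log link.}
#' }
#' An `exponential` convenience family (Weibull with shape fixed at 1) is
#' also accepted.
#'
#' In covariate-adjusted fits the location \eqn{\mu} is a linear predictor
#' \eqn{x'\beta} and the first ancillary (shape) parameter is a linear
#' predictor on its link scale; the generalized gamma's \eqn{Q} is always a
#' scalar.
#'
#' @param t vector of non-negative times.
#' @param family one of `"weibull"`, `"gompertz"`, `"gengamma"`, `"llogis"`,
#'   `"lnorm"`, `"exponential"`.
#' @param mu location parameter, recycled against `t`.
#' @param anc ancillary (shape) parameters on their natural scale: a vector,
#'   or for the generalized gamma a 2-column matrix / length-2 vector
#'   `(sigma, Q)`.
#' @return `ps_surv` and `ps_haz` return numeric vectors; `ps_rtime` returns
#'   event times (possibly `Inf` for defective distributions such as the
#'   Gompertz with negative shape).
#' @name ps_families
NULL

.ps_families <- c("weibull", "gompertz", "gengamma", "llogis", "lnorm",
                  "exponential")

ps_check_family <- function(family) {
  family <- match.arg(family, .ps_families)
  family
}

## number of ancillary parameters and their link functions
ps_family_info <- function(family) {
  family <- ps_check_family(family)
  switch(family,
    weibull     = list(anc_names = "shape", links = "log"),
    gompertz    = list(anc_names = "shape", links = "identity"),
    gengamma    = list(anc_names = c("sigma", "Q"),
                       links = c("log", "identity")),
    llogis      = list(anc_names = "shape", links = "log"),
    lnorm       = list(anc_names = "sdlog", links = "log"),
    exponential = list(anc_names = character(0), links = character(0))
  )
}

.anc_mat <- function(anc, n, k) {
  if (k == 0L) return(matrix(numeric(0), n, 0))
  if (is.null(dim(anc))) {
    if (length(anc) == k) anc <- matrix(anc, n, k, byrow = TRUE)
    else if (k == 1L) anc <- matrix(rep_len(anc, n), n, 1)
    else stop("ancillary parameters must have length ", k,
              " or be an n-by-", k, " matrix")
  }
  if (ncol(anc) != k) stop("expected ", k, " ancillary parameter(s)")
  if (nrow(anc) != n) anc <- anc[rep_len(seq_len(nrow(anc)), n), , drop = FALSE]
  anc
}

## log S(t); t >= 0, vectorized, mu/anc recycled
ps_logS <- function(t, family, mu, anc = NULL) {
  family <- ps_check_family(family)
  n <- max(length(t), length(mu), if (!is.null(dim(anc))) nrow(anc) else 1L)
  t <- rep_len(t, n); mu <- rep_len(mu, n)
  if (any(t < 0)) stop("t must be non-negative")
  k <- length(ps_family_info(family)$anc_names)
  a <- .anc_mat(anc, n, k)
  switch(family,
    exponential = -t * exp(mu),
    weibull = {
      s <- a[, 1]
      -(t / exp(mu))^s
    },
    gompertz = {
      sh <- a[, 1]; rate <- exp(mu)
      ## H(t) = rate * (e^{sh t} - 1)/sh, limit rate*t as sh -> 0
      H <- ifelse(sh == 0, rate * t, rate * expm1(sh * t) / sh)
      -H
    },
    llogis = {
      s <- a[, 1]
      -log1p((t / exp(mu))^s)
    },
    lnorm = {
      sig <- a[, 1]
      out <- pnorm((log(t) - mu) / sig, lower.tail = FALSE, log.p = TRUE)
      out[t == 0] <- 0
      out
    },
    gengamma = {
      sig <- a[, 1]; Q <- a[, 2]
      out <- numeric(n)
      z <- t == 0
      out[z] <- 0
      i <- !z
      if (any(i)) {
        w <- (log(t[i]) - mu[i]) / sig[i]
        Qi <- Q[i]
        small <- abs(Qi) < 1e-4
        o <- numeric(sum(i))
        if (any(small))
          o[small] <- pnorm(w[small], lower.tail = FALSE, log.p = TRUE)
        if (any(!small)) {
          q2 <- Qi[!small]^-2
          x <- q2 * exp(Qi[!small] * w[!small])
          o[!small] <- ifelse(Qi[!small] > 0,
            pgamma(x, q2, lower.tail = FALSE, log.p = TRUE),
            pgamma(x, q2, lower.tail = TRUE, log.p = TRUE))
        }
        out[i] <- o
      }
      out
    })
}

## log h(t); t > 0
ps_logh <- function(t, family, mu, anc = NULL) {
  family <- ps_check_family(family)
  n <- max(length(t), length(mu), if (!is.null(dim(anc))) nrow(anc) else 1L)
  t <- rep_len(t, n); mu <- rep_len(mu, n)
  if (any(t <= 0)) stop("hazard requires t > 0")
  k <- length(ps_family_info(family)$anc_names)
  a <- .anc_mat(anc, n, k)
  switch(family,
    exponential = mu + 0 * t,
    weibull = {
      s <- a[, 1]
      log(s) - mu + (s - 1) * (log(t) - mu)
    },
    gompertz = mu + a[, 1] * t,
    llogis = {
      s <- a[, 1]
      log(s) - mu + (s - 1) * (log(t) - mu) - log1p((t / exp(mu))^s)
    },
    lnorm = {
      sig <- a[, 1]
      w <- (log(t) - mu) / sig
      dnorm(w, log = TRUE) - log(sig) - log(t) -
        pnorm(w, lower.tail = FALSE, log.p = TRUE)
    },
    gengamma = {
      sig <- a[, 1]; Q <- a[, 2]
      w <- (log(t) - mu) / sig
      small <- abs(Q) < 1e-4
      out <- numeric(n)
      if (any(small)) {
        ws <- w[small]; sg <- sig[small]
        out[small] <- dnorm(ws, log = TRUE) - log(sg) - log(t[small]) -
          pnorm(ws, lower.tail = FALSE, log.p = TRUE)
      }
      if (any(!small)) {
        i <- !small
        q2 <- Q[i]^-2
        logf <- log(abs(Q[i])) + q2 * log(q2) +
          q2 * (Q[i] * w[i] - exp(Q[i] * w[i])) - lgamma(q2) -
          log(sig[i]) - log(t[i])
        out[i] <- logf - ps_logS(t[i], "gengamma", mu[i],
                                 cbind(sig[i], Q[i]))
      }
      out
    })
}

#' @rdname ps_families
#' @export
ps_surv <- function(t, family, mu, anc = NULL) exp(ps_logS(t, family, mu, anc))

#' @rdname ps_families
#' @export
ps_haz <- function(t, family, mu, anc = NULL) exp(ps_logh(t, family, mu, anc))

#' @rdname ps_families
#' @param u uniform variates (survival probabilities) to invert, recycled.
#' @export
ps_rtime <- function(u, family, mu, anc = NULL) {
  family <- ps_check_family(family)
  n <- max(length(u), length(mu), if (!is.null(dim(anc))) nrow(anc) else 1L)
  u <- rep_len(u, n); mu <- rep_len(mu, n)
  if (any(u <= 0 | u > 1)) stop("u must be in (0, 1]")
  k <- length(ps_family_info(family)$anc_names)
  a <- .anc_mat(anc, n, k)
  switch(family,
    exponential = -log(u) / exp(mu),
    weibull = exp(mu) * (-log(u))^(1 / a[, 1]),
    gompertz = {
      sh <- a[, 1]; rate <- exp(mu)
      arg <- 1 + sh * (-log(u)) / rate
      out <- ifelse(sh == 0, -log(u) / rate,
                    ifelse(arg > 0, log(pmax(arg, .Machine$double.xmin)) / sh,
                           Inf))
      out
    },
    llogis = {
      s <- a[, 1]
      exp(mu) * ((1 - u) / u)^(1 / s)
    },
    lnorm = exp(mu + a[, 1] * qnorm(u, lower.tail = FALSE)),
    gengamma = {
      sig <- a[, 1]; Q <- a[, 2]
      small <- abs(Q) < 1e-4
      out <- numeric(n)
      if (any(small))
        out[small] <- exp(mu[small] +
          sig[small] * qnorm(u[small], lower.tail = FALSE))
      if (any(!small)) {
        i <- !small
        q2 <- Q[i]^-2
        x <- ifelse(Q[i] > 0, qgamma(u[i], q2, lower.tail = FALSE),
                    qgamma(u[i], q2, lower.tail = TRUE))
        w <- log(x / q2) / Q[i]
        out[i] <- exp(mu[i] + sig[i] * w)
      }
      out
    })
}
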