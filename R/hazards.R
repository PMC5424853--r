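#' Parametric hazard models
#'
#' Constructs a parametric hazard model for one event (or one transition of a
#' multi-state model).  Six baseline families are supported, in the
#' parametrizations conventional for proportional-hazards (PH) and
#' accelerated-failure-time (AFT) survival regression output:
#'
#' \describe{
#'   \item{\code{exponential}}{\code{params = c(log_scale)}; hazard rate
#'     \eqn{\lambda = \exp(-\mathrm{log\_scale})}, \eqn{S(t)=e^{-\lambda t}}.}
#'   \item{\code{weibull}}{fitted (time-scale) form,
#'     \code{params = c(log_scale, log_shape)};
#'     \eqn{S(t)=\exp\{-(t/e^{s})^{e^{k}}\}}.}
#'   \item{\code{weibull_ph}}{rate (linearized) form,
#'     \code{params = c(log_rate, shape)}; \eqn{S(t)=\exp(-e^{a} t^{b})}.
#'     This is the form produced by back-transforming the tail regression
#'     \eqn{\log(-\log S) = a + b\log t}.}
#'   \item{\code{gompertz}}{\code{params = c(shape, log_rate)}; hazard
#'     \eqn{h(t)=e^{c} e^{g t}} with shape \eqn{g} and log baseline rate
#'     \eqn{c}.  Regression output that prints a Gompertz "log(scale)" is read
#'     here as the log baseline rate.}
#'   \item{\code{loglogistic}}{AFT location-scale,
#'     \code{params = c(log_scale, log_shape)};
#'     \eqn{S(t) = 1/(1 + (t/e^{s})^{e^{k}})}.}
#'   \item{\code{lognormal}}{\code{params = c(meanlog, sdlog)}.}
#'   \item{\code{gengamma}}{three-parameter generalized gamma
#'     \code{params = c(mu, sigma, Q)}; \code{Q = 1} recovers the Weibull,
#'     \code{Q = 0} the log-normal.}
#' }
#'
#' Covariates act multiplicatively on the hazard for \code{effect_type =
#' "PH"} (coefficients are log hazard ratios) and as a location shift on the
#' log-time scale for \code{effect_type = "AFT"} (so \eqn{S(t|x) =
#' S_0(t e^{-\beta x})}).
#'
#' @param family One of \code{"exponential"}, \code{"weibull"},
#'   \code{"weibull_ph"}, \code{"gompertz"}, \code{"loglogistic"},
#'   \code{"lognormal"}, \code{"gengamma"}.
#' @param params Named or positional numeric vector of baseline parameters
#'   (see Details).
#' @param coefficients Optional named numeric vector of covariate effects.
#' @param standard_errors Optional named numeric vector of standard errors
#'   for \code{coefficients} (and/or baseline parameters).
#' @param effect_type \code{"PH"} or \code{"AFT"}.  Defaults to \code{"AFT"}
#'   for the log-logistic and log-normal families and \code{"PH"} otherwise.
#' @return An object of class \code{"hazard_model"}.
#' @examples
#' m <- hazard_model("exponential", c(log_scale = 2.753),
#'                   coefficients = c(treat = -0.284))
#' hsurv(m, 3.6, covariates = c(treat = 0))
#' @export
hazard_model <- function(family, params, coefficients = NULL,
                         standard_errors = NULL, effect_type = NULL) {
  family <- match.arg(family, c("exponential", "weibull", "weibull_ph",
                                "gompertz", "loglogistic", "lognormal",
                                "gengamma"))
  npar <- switch(family, exponential = 1L, weibull = 2L, weibull_ph = 2L,
                 gompertz = 2L, loglogistic = 2L, lognormal = 2L,
                 gengamma = 3L)
  params <- as.numeric(params)
  if (length(params) != npar)
    stop("family '", family, "' needs ", npar, " baseline parameter(s), got ",
         length(params))
  if (family == "gengamma" && params[2] <= 0)
    stop("gengamma sigma must be positive")
  if (is.null(effect_type))
    effect_type <- if (family %in% c("loglogistic", "lognormal")) "AFT" else "PH"
  effect_type <- match.arg(effect_type, c("PH", "AFT"))
  if (!is.null(coefficients) && is.null(names(coefficients)))
    stop("'coefficients' must be named")
  structure(list(family = family, params = params,
                 coefficients = coefficients,
                 standard_errors = standard_errors,
                 effect_type = effect_type),
            class = "hazard_model")
}

#' @export
print.hazard_model <- function(x, ...) {
  cat("Parametric hazard model:", x$family,
      sprintf("(%s)", x$effect_type), "\n")
  cat("  baseline params:", paste(signif(x$params, 6), collapse = ", "), "\n")
  if (!is.null(x$coefficients)) {
    cat("  coefficients:\n")
    for (nm in names(x$coefficients))
      cat(sprintf("    %s = %.4g (HR %.4g)\n", nm, x$coefficients[[nm]],
                  exp(x$coefficients[[nm]])))
  }
  invisible(x)
}

## linear predictor sum(beta * x); errors on missing covariates
.lp <- function(model, covariates) {
  if (is.null(model$coefficients)) return(0)
  nm <- names(model$coefficients)
  if (is.null(covariates) || !all(nm %in% names(covariates)))
    stop("missing covariate value(s): ",
         paste(setdiff(nm, names(covariates)), collapse = ", "))
  sum(unlist(model$coefficients) * unlist(covariates[nm]))
}

## baseline cumulative hazard, vectorized in t
.H0 <- function(model, t) {
  p <- model$params
  switch(model$family,
    exponential = exp(-p[1]) * t,
    weibull     = (t / exp(p[1]))^exp(p[2]),
    weibull_ph  = exp(p[1]) * t^p[2],
    gompertz    = if (abs(p[1]) < 1e-12) exp(p[2]) * t
                  else (exp(p[2]) / p[1]) * (exp(p[1] * t) - 1),
    loglogistic = log1p((t / exp(p[1]))^exp(p[2])),
    lognormal   = -stats::pnorm((log(t) - p[1]) / p[2], lower.tail = FALSE,
                                log.p = TRUE),
    gengamma    = -.sgengamma(t, p[1], p[2], p[3], log.p = TRUE)
  )
}

## baseline hazard h0(t)
.h0 <- function(model, t) {
  p <- model$params
  switch(model$family,
    exponential = rep(exp(-p[1]), length(t)),
    weibull     = {
      sh <- exp(p[2]); sc <- exp(p[1])
      (sh / sc) * (t / sc)^(sh - 1)
    },
    weibull_ph  = exp(p[1]) * p[2] * t^(p[2] - 1),
    gompertz    = exp(p[2]) * exp(p[1] * t),
    loglogistic = {
      sh <- exp(p[2]); sc <- exp(p[1])
      ((sh / sc) * (t / sc)^(sh - 1)) / (1 + (t / sc)^sh)
    },
    lognormal   = {
      z <- (log(t) - p[1]) / p[2]
      stats::dnorm(z) / (t * p[2] * stats::pnorm(z, lower.tail = FALSE))
    },
    gengamma    = .dgengamma(t, p[1], p[2], p[3]) /
                  .sgengamma(t, p[1], p[2], p[3])
  )
}

## generalized gamma (mu, sigma, Q): survival and density
.sgengamma <- function(t, mu, sigma, Q, log.p = FALSE) {
  w <- (log(t) - mu) / sigma
  if (abs(Q) < 1e-8) {
    out <- stats::pnorm(w, lower.tail = FALSE, log.p = log.p)
  } else {
    u <- exp(Q * w) / Q^2
    out <- stats::pgamma(u, shape = 1 / Q^2, lower.tail = (Q < 0),
                         log.p = log.p)
  }
  out
}

.dgengamma <- function(t, mu, sigma, Q) {
  w <- (log(t) - mu) / sigma
  if (abs(Q) < 1e-8) return(stats::dlnorm(t, mu, sigma))
  u <- exp(Q * w) / Q^2
  abs(Q) / (sigma * t) * stats::dgamma(u, shape = 1 / Q^2) * u
}

.check_t <- function(t) {
  if (any(!is.finite(t) & !is.infinite(t)) || any(t < 0, na.rm = TRUE))
    stop("'t' must be non-negative")
}

#' Cumulative hazard of a parametric model
#'
#' @param model A \code{\link{hazard_model}}.
#' @param t Non-negative time(s), in years.
#' @param covariates Named list/vector with a value for every model
#'   coefficient (may be omitted when the model has none).
#' @return \eqn{H(t|x)}, vectorized over \code{t}.  For PH models
#'   \eqn{H(t|x) = e^{\beta x} H_0(t)}; for AFT models
#'   \eqn{H(t|x) = H_0(t e^{-\beta x})}.
#' @export
hcumhaz <- function(model, t, covariates = NULL) {
  .check_t(t)
  lp <- .lp(model, covariates)
  out <- if (model$effect_type == "PH") exp(lp) * .H0(model, t)
         else .H0(model, t * exp(-lp))
  out[t == 0] <- 0
  out
}

#' Hazard function of a parametric model
#'
#' @inheritParams hcumhaz
#' @return \eqn{h(t|x)}, vectorized over \code{t}.
#' @export
hhaz <- function(model, t, covariates = NULL) {
  .check_t(t)
  lp <- .lp(model, covariates)
  if (model$effect_type == "PH") exp(lp) * .h0(model, t)
  else exp(-lp) * .h0(model, t * exp(-lp))
}

#' Survival function of a parametric model
#'
#' @inheritParams hcumhaz
#' @return \eqn{S(t|x) = \exp\{-H(t|x)\}}, in \eqn{[0,1]}.
#' @export
hsurv <- function(model, t, covariates = NULL) {
  exp(-hcumhaz(model, t, covariates))
}

#' Inverse cumulative hazard
#'
#' Returns the smallest \eqn{t} with \eqn{H(t|x) = H}.  Used for exact event
#' time sampling (\eqn{T = H^{-1}(-\log U)}).  For families with bounded total
#' hazard (Gompertz with negative shape) a draw exceeding
#' \eqn{H(\infty)} corresponds to an event that never happens and
#' \code{Inf} is returned.
#'
#' @param model A \code{\link{hazard_model}}.
#' @param H Non-negative cumulative hazard value(s).
#' @param covariates As in \code{\link{hcumhaz}}.
#' @return Time(s) in years; \code{Inf} where the event never occurs.
#' @export
hinvcumhaz <- function(model, H, covariates = NULL) {
  if (any(H < 0)) stop("'H' must be non-negative")
  lp <- .lp(model, covariates)
  ## reduce to baseline inversion
  if (model$effect_type == "PH") {
    H0 <- H / exp(lp)
    tacc <- 1
  } else {
    H0 <- H
    tacc <- exp(lp)
  }
  p <- model$params
  t0 <- switch(model$family,
    exponential = H0 * exp(p[1]),
    weibull     = exp(p[1]) * H0^(1 / exp(p[2])),
    weibull_ph  = (H0 / exp(p[1]))^(1 / p[2]),
    gompertz    = {
      if (abs(p[1]) < 1e-12) H0 / exp(p[2])
      else {
        arg <- 1 + p[1] * H0 / exp(p[2])
        out <- rep(Inf, length(arg))
        pos <- arg > 0
        out[pos] <- log(arg[pos]) / p[1]
        out
      }
    },
    loglogistic = exp(p[1]) * (expm1(H0))^(1 / exp(p[2])),
    lognormal   = exp(p[1] + p[2] * stats::qnorm(-H0, log.p = TRUE,
                                                 lower.tail = FALSE)),
    gengamma    = {
      if (abs(p[3]) < 1e-8)
        exp(p[1] + p[2] * stats::qnorm(-H0, log.p = TRUE,
                                       lower.tail = FALSE))
      else {
        u <- stats::qgamma(-H0, shape = 1 / p[3]^2,
                           lower.tail = (p[3] < 0), log.p = TRUE)
        exp(p[1] + (p[2] / p[3]) * log(p[3]^2 * u))
      }
    }
  )
  out <- t0 * tacc
  out[H == 0] <- 0
  out
}

#' Hazard ratio and Wald confidence interval from a log-hazard coefficient
#'
#' @param coefficient Log hazard-ratio estimate.
#' @param se Optional positive standard error; when supplied a Wald interval
#'   \eqn{\exp(\beta \pm z_{1-\alpha/2}\,\mathrm{se})} is returned.
#' @param level Confidence level (default 0.95).
#' @return A list with \code{hr} and, when \code{se} is given, \code{ci_low}
#'   and \code{ci_high}.
#' @examples
#' hazard_ratio(-0.519, 0.117)   # 0.595 (0.473, 0.748)
#' @export
hazard_ratio <- function(coefficient, se = NULL, level = 0.95) {
  stopifnot(is.finite(coefficient), level > 0, level < 1)
  out <- list(hr = exp(coefficient))
  if (!is.null(se)) {
    if (se <= 0) stop("'se' must be positive")
    z <- stats::qnorm(1 - (1 - level) / 2)
    out$ci_low <- exp(coefficient - z * se)
    out$ci_high <- exp(coefficient + z * se)
  }
  out
}
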