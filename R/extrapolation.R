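#' Survival curve on a time grid
#'
#' Lightweight container pairing a time grid with survival probabilities.
#'
#' @param time Non-decreasing time grid (years).
#' @param surv Survival probabilities in \eqn{[0,1]}.
#' @return Object of class \code{"survival_curve"}.
#' @export
survival_curve <- function(time, surv) {
  stopifnot(length(time) == length(surv), !is.unsorted(time),
            all(surv >= -1e-12 & surv <= 1 + 1e-12))
  structure(list(time = time, surv = pmin(pmax(surv, 0), 1)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve on [%g, %g], %d points\n",
              min(x$time), max(x$time), length(x$time)))
  invisible(x)
}

#' Fit a parametric tail to a Kaplan-Meier curve by linearized regression
#'
#' Transforms the Kaplan-Meier step points at and after \code{tail_start} so
#' that the chosen family is linear in (a function of) time, fits ordinary
#' least squares, and back-transforms:
#' \itemize{
#'   \item exponential: \eqn{\log S = -\lambda t}, regression through the
#'     origin of \eqn{\log S} on \eqn{t}; slope \eqn{= -\lambda}.
#'   \item weibull: \eqn{\log(-\log S) = a + b \log t}; intercept
#'     \eqn{a = \log\lambda}, slope \eqn{b} = shape, giving
#'     \eqn{S(t) = \exp(-e^{a} t^{b})}.
#' }
#' Points with \eqn{S = 0} or \eqn{S = 1} (transform undefined) are dropped
#' with a warning.  One point per distinct event time is used, unweighted.
#'
#' @param km A \code{\link{km_fit}} result.
#' @param tail_start Time from which the tail is taken (years).
#' @param family \code{"weibull"} or \code{"exponential"}.
#' @param time_mode \code{"absolute"} (default): regression times are study
#'   times; \code{"from_start"}: times are measured from \code{tail_start}.
#' @return Object of class \code{"tail_fit"}: list with \code{family},
#'   \code{tail_start}, \code{time_mode}, \code{coef} (regression scale),
#'   \code{model} (a \code{\link{hazard_model}}), and the points used.
#' @export
fit_tail <- function(km, tail_start, family = c("weibull", "exponential"),
                     time_mode = c("absolute", "from_start")) {
  family <- match.arg(family)
  time_mode <- match.arg(time_mode)
  stopifnot(tail_start >= 0)
  keep <- km$time >= tail_start & km$n.event > 0
  tt <- km$time[keep]
  ss <- km$surv[keep]
  if (time_mode == "from_start") tt <- tt - tail_start
  bad <- ss <= 0 | ss >= 1 | tt <= 0
  if (any(bad)) {
    warning(sum(bad), " tail point(s) with undefined transform excluded")
    tt <- tt[!bad]; ss <- ss[!bad]
  }
  if (length(tt) < 2) stop("fewer than 2 usable tail points")
  if (family == "exponential") {
    slope <- sum(tt * log(ss)) / sum(tt^2)         # through the origin
    cf <- c(slope = slope)
    model <- hazard_model("exponential", c(log_scale = -log(-slope)))
  } else {
    fit <- stats::lm.fit(cbind(1, log(tt)), log(-log(ss)))
    cf <- c(a = unname(fit$coefficients[1]), b = unname(fit$coefficients[2]))
    model <- hazard_model("weibull_ph", c(log_rate = cf[["a"]],
                                          shape = cf[["b"]]))
  }
  structure(list(family = family, tail_start = tail_start,
                 time_mode = time_mode, coef = cf, model = model,
                 points = data.frame(time = tt, surv = ss)),
            class = "tail_fit")
}

#' Evaluate a tail fit at study times
#'
#' @param tail A \code{\link{fit_tail}} result.
#' @param t Study time(s) in years.
#' @return Extrapolated survival probabilities (in \code{"from_start"} mode
#'   the model is evaluated at \code{t - tail_start}, floored at zero).
#' @export
tail_surv <- function(tail, t) {
  tt <- if (tail$time_mode == "from_start") pmax(t - tail$tail_start, 0) else t
  hsurv(tail$model, tt)
}

#' Choose the latest tail start whose extrapolation reaches zero
#'
#' Considers every distinct observed event time as a candidate start for the
#' tail regression and returns the latest one whose fitted extrapolation
#' satisfies \eqn{S(\mathrm{horizon}) \le \mathrm{zero\_tol}}.
#'
#' @param km A \code{\link{km_fit}} result.
#' @param family Tail family, as in \code{\link{fit_tail}}.
#' @param horizon Extrapolation horizon in years (default 15).
#' @param zero_tol Threshold below which the extrapolation counts as having
#'   reached zero (default 0.005; no Weibull is exactly zero at finite time).
#' @param time_mode Passed to \code{\link{fit_tail}}.
#' @return List with \code{tail_start} (\code{NA} if no candidate qualifies),
#'   \code{fit} (the corresponding \code{tail_fit}), and the candidate table.
#' @export
select_tail_start <- function(km, family = "weibull", horizon = 15,
                              zero_tol = 0.005, time_mode = "absolute") {
  cand <- unique(km$time[km$n.event > 0])
  rows <- lapply(cand, function(ts) {
    fit <- tryCatch(suppressWarnings(fit_tail(km, ts, family, time_mode)),
                    error = function(e) NULL)
    if (is.null(fit)) return(data.frame(tail_start = ts, s_horizon = NA,
                                        qualifies = FALSE))
    sh <- tail_surv(fit, horizon)
    data.frame(tail_start = ts, s_horizon = sh,
               qualifies = is.finite(sh) && sh <= zero_tol)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$tail_start[tab$qualifies]
  if (length(ok) == 0)
    return(list(tail_start = NA_real_, fit = NULL, candidates = tab))
  ts <- max(ok)
  list(tail_start = ts,
       fit = suppressWarnings(fit_tail(km, ts, family, time_mode)),
       candidates = tab)
}

#' Map a survival curve through a hazard ratio
#'
#' Proportional-hazards mapping \eqn{S_{new}(t) = S_{ref}(t)^{hr}}, i.e.
#' multiplying the log survival probabilities by the hazard ratio and
#' exponentiating.
#'
#' @param curve A \code{\link{survival_curve}}.
#' @param hr Positive hazard ratio.
#' @return A new \code{survival_curve}.
#' @export
map_by_hazard_ratio <- function(curve, hr) {
  if (hr <= 0) stop("'hr' must be positive")
  survival_curve(curve$time, curve$surv^hr)
}

#' Stitch an observed-period model to an extrapolated tail
#'
#' Evaluates the observed-period model on grid points up to \code{junction}
#' and the tail beyond it, recording the discontinuity at the junction (the
#' gap is reported, not repaired; optionally the tail can be renormalized to
#' be continuous by conditional-survival multiplication).
#'
#' @param observed A \code{hazard_model}, function of time, or
#'   \code{survival_curve} for the observed period.
#' @param tail A \code{tail_fit}, \code{hazard_model}, or function of time
#'   for the extrapolated period.
#' @param junction Changeover time in years.
#' @param grid Evaluation grid covering \code{[0, horizon]}.
#' @param covariates Covariates for \code{observed} when it is a
#'   \code{hazard_model}.
#' @param renormalize If \code{TRUE}, scale the tail so the curve is
#'   continuous at the junction (off by default).
#' @return A \code{survival_curve} with attribute \code{"junction_gap"}.
#' @export
stitch <- function(observed, tail, junction, grid, covariates = NULL,
                   renormalize = FALSE) {
  ev <- function(obj, t) {
    if (inherits(obj, "tail_fit")) tail_surv(obj, t)
    else if (inherits(obj, "hazard_model")) hsurv(obj, t, covariates)
    else if (inherits(obj, "survival_curve"))
      stats::approx(obj$time, obj$surv, xout = t, rule = 2)$y
    else if (is.function(obj)) obj(t)
    else stop("cannot evaluate curve object")
  }
  s_obs_j <- ev(observed, junction)
  s_tail_j <- ev(tail, junction)
  gap <- s_tail_j - s_obs_j
  surv <- ifelse(grid <= junction, ev(observed, grid), ev(tail, grid))
  if (renormalize) {
    idx <- grid > junction
    surv[idx] <- s_obs_j * ev(tail, grid[idx]) / s_tail_j
    gap <- 0
  }
  out <- survival_curve(grid, surv)
  attr(out, "junction_gap") <- gap
  out
}
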