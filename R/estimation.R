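#' Kaplan-Meier estimate
#'
#' Product-limit estimator, wrapping \code{survival::survfit}.  Deaths are
#' processed before censorings at tied times (the \code{survival} convention).
#'
#' @param time Positive event/censoring times.
#' @param status Event indicator (1 = event, 0 = censored).
#' @param conf.int Confidence level for the log-log pointwise interval, or
#'   \code{NULL} for none.
#' @return An object of class \code{"km_estimate"}: a list with \code{time},
#'   \code{surv}, \code{n.risk}, \code{n.event}, and optionally
#'   \code{ci_low}/\code{ci_high}, at the distinct observed times.
#' @export
km_fit <- function(time, status, conf.int = NULL) {
  if (length(time) == 0) stop("empty input")
  if (any(time <= 0)) stop("times must be positive")
  fit <- survival::survfit(survival::Surv(time, status) ~ 1,
                           conf.type = if (is.null(conf.int)) "none"
                                       else "log-log",
                           conf.int = if (is.null(conf.int)) 0.95
                                      else conf.int)
  out <- list(time = fit$time, surv = fit$surv, n.risk = fit$n.risk,
              n.event = fit$n.event)
  if (!is.null(conf.int)) {
    out$ci_low <- fit$lower
    out$ci_high <- fit$upper
  }
  structure(out, class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate:", length(x$time), "distinct times,",
      sum(x$n.event), "events\n")
  invisible(x)
}

#' Evaluate a Kaplan-Meier estimate as a step function
#'
#' Right-continuous evaluation with \eqn{S(0) = 1} and the last value
#' carried forward.
#'
#' @param km A \code{\link{km_fit}} result.
#' @param t Evaluation time(s).
#' @return Survival probabilities at \code{t}.
#' @export
km_step <- function(km, t) {
  stats::approx(c(0, km$time), c(1, km$surv), xout = t, method = "constant",
                rule = 2, f = 0)$y
}

#' Restricted mean survival time from a Kaplan-Meier estimate
#'
#' Area under the Kaplan-Meier step function up to \code{horizon}.  Beyond the
#' last observed time the curve is carried forward flat.
#'
#' @param km A \code{\link{km_fit}} result.
#' @param horizon Upper limit of integration (same time unit as the data).
#' @return Restricted mean, in time units.
#' @export
km_restricted_mean <- function(km, horizon) {
  stopifnot(horizon > 0)
  tt <- c(0, km$time[km$time < horizon], horizon)
  ss <- c(1, km$surv[km$time < horizon])      # value on each interval
  sum(ss * diff(tt))
}

#' Convert an event rate to a per-cycle probability (and back)
#'
#' Under a constant hazard \code{rate}, the probability of the event within
#' one cycle is \eqn{p = 1 - e^{-\mathrm{rate}\cdot\mathrm{cycle}}}.
#'
#' @param rate Non-negative hazard rate (events per unit time).
#' @param cycle Cycle length (same time unit); default 1.
#' @return A probability in \eqn{[0,1)}.
#' @examples
#' rate_to_probability(1 / 24.1791)   # monthly probability 0.0405
#' @export
rate_to_probability <- function(rate, cycle = 1) {
  if (any(rate < 0)) stop("'rate' must be non-negative")
  -expm1(-rate * cycle)
}

#' @rdname rate_to_probability
#' @param p Probability in \eqn{[0,1)}.
#' @export
probability_to_rate <- function(p, cycle = 1) {
  if (any(p < 0 | p >= 1)) stop("'p' must be in [0,1)")
  -log1p(-p) / cycle
}

#' Competing-risks cumulative incidence (Aalen-Johansen)
#'
#' @param time Positive times to first event or censoring.
#' @param cause Integer cause codes: 0 = censored, 1, 2, ... = competing
#'   event types.
#' @return A list with \code{time} (distinct event times), a matrix
#'   \code{cuminc} (one column per cause), and \code{km} (all-cause
#'   Kaplan-Meier survival at the same times).  At every time the incidences
#'   sum to one minus the all-cause survival.
#' @export
cuminc_fit <- function(time, cause) {
  if (length(time) == 0) stop("empty input")
  causes <- sort(unique(cause[cause != 0]))
  if (length(causes) == 0) {
    ut <- sort(unique(time))
    return(list(time = ut,
                cuminc = matrix(0, length(ut), 0), km = rep(1, length(ut))))
  }
  f <- survival::survfit(survival::Surv(time, factor(cause,
                           levels = c(0, causes))) ~ 1)
  ## survfit pstate columns: initial state then one per cause
  ci <- f$pstate[, -1, drop = FALSE]
  colnames(ci) <- as.character(causes)
  list(time = f$time, cuminc = ci, km = f$pstate[, 1])
}

# ---------------------------------------------------------------------------
# counting-process records and IPD conversion

#' Convert wide individual-patient data to transition records
#'
#' The wide format has one row per subject with columns \code{id},
#' \code{arm} (0 = control, 1 = treated), \code{t_progression},
#' \code{t_death} (\code{NA} when unobserved) and \code{t_censor}.  Records
#' are produced for the three illness-death transitions: 1 = progression-free
#' to progression, 2 = progression-free to death, 3 = progression to death.
#' Transitions out of progression-free use the study clock from 0; the
#' progression-to-death transition uses the clock stated by \code{clock23}:
#' \code{"reset"} (time since progression; semi-Markov) or \code{"forward"}
#' (study time with delayed entry at progression; Markov).  The arrival time
#' in the originating state on the study clock is carried in \code{arrival}.
#'
#' @param ipd Data frame in the wide schema above.
#' @param clock23 \code{"reset"} or \code{"forward"}.
#' @return Data frame of class \code{"transition_records"} with columns
#'   \code{id}, \code{trans}, \code{tstart}, \code{tstop}, \code{status},
#'   \code{treat}, \code{arrival}.
#' @export
ipd_to_records <- function(ipd, clock23 = c("reset", "forward")) {
  clock23 <- match.arg(clock23)
  need <- c("id", "arm", "t_progression", "t_death", "t_censor")
  if (!all(need %in% names(ipd)))
    stop("ipd must have columns: ", paste(need, collapse = ", "))
  tp <- ipd$t_progression; td <- ipd$t_death; tc <- ipd$t_censor
  prog <- !is.na(tp)
  died <- !is.na(td)
  ## exit time from the progression-free state
  exit_pf <- ifelse(prog, tp, ifelse(died, td, tc))
  rec1 <- data.frame(id = ipd$id, trans = 1L, tstart = 0, tstop = exit_pf,
                     status = as.integer(prog), treat = ipd$arm, arrival = 0)
  rec2 <- data.frame(id = ipd$id, trans = 2L, tstart = 0, tstop = exit_pf,
                     status = as.integer(!prog & died), treat = ipd$arm,
                     arrival = 0)
  ip <- which(prog)
  stop3 <- ifelse(died[ip], td[ip], tc[ip])
  rec3 <- data.frame(id = ipd$id[ip], trans = 3L,
                     tstart = if (clock23 == "reset") 0 else tp[ip],
                     tstop = if (clock23 == "reset") stop3 - tp[ip]
                             else stop3,
                     status = as.integer(died[ip]),
                     treat = ipd$arm[ip], arrival = tp[ip])
  out <- rbind(rec1, rec2, rec3)
  out <- out[out$tstop > out$tstart, ]
  class(out) <- c("transition_records", "data.frame")
  out
}

#' Read wide individual-patient data from a delimited file
#'
#' @param path Path to a CSV file in the schema of
#'   \code{\link{ipd_to_records}}.
#' @return Data frame.
#' @export
read_ipd <- function(path) {
  ipd <- utils::read.csv(path)
  need <- c("id", "arm", "t_progression", "t_death", "t_censor")
  if (!all(need %in% names(ipd)))
    stop("IPD file must have columns: ", paste(need, collapse = ", "))
  ipd
}

# ---------------------------------------------------------------------------
# parametric maximum likelihood on counting-process data

## optimization scale: transform constrained parameters so optim is
## unconstrained.  Only weibull_ph (shape>0), lognormal (sdlog>0) and
## gengamma (sigma>0) have constraints under our parametrizations.
.to_opt <- function(family, p) {
  switch(family,
    weibull_ph = c(p[1], log(p[2])),
    lognormal  = c(p[1], log(p[2])),
    gengamma   = c(p[1], log(p[2]), p[3]),
    p)
}
.from_opt <- function(family, q) {
  switch(family,
    weibull_ph = c(q[1], exp(q[2])),
    lognormal  = c(q[1], exp(q[2])),
    gengamma   = c(q[1], exp(q[2]), q[3]),
    q)
}
.npar <- function(family)
  switch(family, exponential = 1L, gengamma = 3L, 2L)

## crude moment-based starting values from uncensored exposure
.init_params <- function(family, records) {
  expo <- sum(records$tstop - records$tstart)
  ev <- sum(records$status)
  rate <- max(ev, 0.5) / expo
  mt <- records$tstop[records$status == 1]
  if (length(mt) == 0) mt <- records$tstop
  switch(family,
    exponential = -log(rate),
    weibull     = c(log(1 / rate), 0),
    weibull_ph  = c(log(rate), 1),
    gompertz    = c(0, log(rate)),
    loglogistic = c(log(stats::median(mt)), 0),
    lognormal   = c(mean(log(mt)), max(stats::sd(log(mt)), 0.5)),
    gengamma    = c(mean(log(mt)), max(stats::sd(log(mt)), 0.5), 1))
}

#' Fit a parametric transition model by maximum likelihood
#'
#' Maximizes the counting-process log-likelihood
#' \deqn{\ell = \sum_i d_i \log h(t_i^{stop}|x_i) -
#'   \{H(t_i^{stop}|x_i) - H(t_i^{start}|x_i)\}}
#' over baseline parameters and covariate coefficients, which accommodates
#' right censoring and left truncation (delayed entry) directly.  Standard
#' errors come from the numerically differentiated observed information.
#'
#' @param records Transition records (see \code{\link{ipd_to_records}}) for a
#'   single transition: columns \code{tstart}, \code{tstop}, \code{status}
#'   and any covariate columns named in \code{covariates}.
#' @param family Baseline family (see \code{\link{hazard_model}}).
#' @param covariates Character vector of covariate column names (PH log
#'   hazard ratios, or AFT effects for the log-logistic/log-normal families);
#'   default none.
#' @param init Optional starting values on the natural scale
#'   (baseline params, then coefficients).
#' @return A \code{\link{hazard_model}} with extra fields \code{loglik},
#'   \code{se} (all parameters), \code{vcov}, \code{n}, \code{nevent}, and
#'   class \code{c("transition_fit", "hazard_model")}.
#' @export
fit_parametric <- function(records, family, covariates = character(),
                           init = NULL) {
  stopifnot(all(c("tstart", "tstop", "status") %in% names(records)))
  if (sum(records$status) < 1) stop("no events in 'records'")
  if (any(records$tstop <= records$tstart)) stop("tstop must exceed tstart")
  family <- match.arg(family, c("exponential", "weibull", "weibull_ph",
                                "gompertz", "loglogistic", "lognormal",
                                "gengamma"))
  nb <- .npar(family)
  X <- if (length(covariates))
         as.matrix(records[, covariates, drop = FALSE]) else NULL
  d <- records$status
  t1 <- records$tstart
  t2 <- records$tstop
  effect_type <- if (family %in% c("loglogistic", "lognormal")) "AFT" else "PH"

  negll <- function(q) {
    p <- .from_opt(family, q[seq_len(nb)])
    beta <- if (length(covariates)) q[-seq_len(nb)] else NULL
    m <- tryCatch(hazard_model(family, p, effect_type = effect_type),
                  error = function(e) NULL)
    if (is.null(m)) return(1e10)
    lp <- if (is.null(X)) 0 else drop(X %*% beta)
    H0_at <- function(tt) {                      # H0 with H0(0)=0, no warnings
      out <- numeric(length(tt))
      pos <- tt > 0
      if (any(pos)) out[pos] <- .H0(m, tt[pos])
      out
    }
    if (effect_type == "PH") {
      lh <- log(.h0(m, t2)) + lp
      H <- exp(lp) * (H0_at(t2) - H0_at(t1))
    } else {
      acc <- exp(-lp)
      lh <- log(.h0(m, t2 * acc)) - lp
      H <- H0_at(t2 * acc) - H0_at(t1 * acc)
    }
    ll <- sum(d * lh) - sum(H)
    if (!is.finite(ll)) 1e10 else -ll
  }

  p0 <- if (is.null(init)) c(.init_params(family, records),
                             rep(0, length(covariates)))
        else init
  q0 <- c(.to_opt(family, p0[seq_len(nb)]), p0[-seq_len(nb)])
  opt <- stats::optim(q0, negll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("likelihood optimization did not converge (code ",
         opt$convergence, ")")
  qhat <- opt$par
  phat <- .from_opt(family, qhat[seq_len(nb)])
  beta <- if (length(covariates)) {
    b <- qhat[-seq_len(nb)]; names(b) <- covariates; b
  } else NULL

  ## delta method back to the natural scale
  vcov_opt <- tryCatch(solve(opt$hessian), error = function(e)
    matrix(NA_real_, length(qhat), length(qhat)))
  J <- diag(length(qhat))
  tr_idx <- switch(family, weibull_ph = 2L, lognormal = 2L, gengamma = 2L,
                   integer(0))
  for (i in tr_idx) J[i, i] <- phat[i]           # d/dq exp(q) = exp(q)
  vcov_nat <- J %*% vcov_opt %*% t(J)
  se <- sqrt(pmax(diag(vcov_nat), 0))
  names(se) <- c(paste0("p", seq_len(nb)), covariates)

  m <- hazard_model(family, phat, coefficients = beta,
                    standard_errors = if (length(covariates))
                      se[covariates] else NULL,
                    effect_type = effect_type)
  m$loglik <- -opt$value
  m$se <- se
  m$vcov <- vcov_nat
  m$n <- nrow(records)
  m$nevent <- sum(d)
  class(m) <- c("transition_fit", "hazard_model")
  m
}

#' Akaike information criterion of a fitted transition model
#'
#' \eqn{AIC = -2\ell + 2k}.  Comparable only between models fitted to the
#' same records on the same time scale (the likelihood carries a Jacobian
#' under time rescaling).
#'
#' @param fit A \code{\link{fit_parametric}} result.
#' @return AIC value.
#' @export
aic <- function(fit) {
  k <- length(fit$params) + length(fit$coefficients)
  -2 * fit$loglik + 2 * k
}

#' Cox-Snell residuals of a fitted transition model
#'
#' \eqn{r_i = H(t_i^{stop}|x_i) - H(t_i^{start}|x_i)}, carrying the censoring
#' status.  Under a correctly specified model the residuals behave as a
#' unit-exponential censored sample: the Kaplan-Meier estimate of the
#' residuals should track \eqn{\exp(-r)}.
#'
#' @param fit A \code{\link{fit_parametric}} result.
#' @param records The records the model was fitted to.
#' @return Data frame with \code{residual} and \code{status}.
#' @export
cox_snell <- function(fit, records) {
  cov_nm <- names(fit$coefficients)
  H <- vapply(seq_len(nrow(records)), function(i) {
    cv <- if (length(cov_nm)) as.list(records[i, cov_nm, drop = FALSE])
          else NULL
    hcumhaz(fit, records$tstop[i], cv) -
      (if (records$tstart[i] > 0) hcumhaz(fit, records$tstart[i], cv) else 0)
  }, numeric(1))
  data.frame(residual = H, status = records$status)
}

#' State-arrival check of the Markov assumption
#'
#' Fits a Cox proportional-hazards model (Breslow ties) to the
#' progression-to-death records on the study clock with delayed entry at the
#' progression time, including the arrival (progression) time as a covariate
#' alongside treatment.  A non-zero arrival coefficient is evidence that the
#' transition hazard depends on when the state was entered, i.e. against the
#' Markov property.
#'
#' @param records Transition-3 records in clock-forward form
#'   (\code{tstart} = arrival, \code{tstop} = study exit time), with columns
#'   \code{treat} and \code{arrival}.
#' @param baseline \code{"cox"} (default) or a parametric family name, in
#'   which case the check is run through \code{\link{fit_parametric}} with a
#'   parametric baseline instead.
#' @return List with \code{beta_arrival}, \code{se}, \code{p}.
#' @export
state_arrival_check <- function(records, baseline = "cox") {
  if (sum(records$status) < 2) stop("need at least 2 events")
  if (stats::var(records$arrival) == 0)
    stop("arrival time is constant across subjects; check is degenerate")
  if (identical(baseline, "cox")) {
    fit <- survival::coxph(
      survival::Surv(tstart, tstop, status) ~ treat + arrival,
      data = records, ties = "breslow")
    s <- summary(fit)$coefficients
    list(beta_arrival = unname(s["arrival", "coef"]),
         se = unname(s["arrival", "se(coef)"]),
         p = unname(s["arrival", "Pr(>|z|)"]))
  } else {
    fit <- fit_parametric(records, baseline, c("treat", "arrival"))
    b <- fit$coefficients[["arrival"]]
    se <- fit$standard_errors[["arrival"]]
    list(beta_arrival = b, se = se,
         p = 2 * stats::pnorm(-abs(b / se)))
  }
}

#' Bootstrap pointwise percentile band for a proportion-in-state curve
#'
#' Resamples subjects (with replacement, within treatment arm) from wide IPD
#' and recomputes a time-indexed statistic on each resample.
#'
#' @param ipd Wide IPD (see \code{\link{ipd_to_records}}).
#' @param statistic Function \code{(ipd, grid) -> numeric} returning the
#'   curve on \code{grid} (e.g. observed proportion in progression).
#' @param grid Evaluation times.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param level Band level (default 0.95).
#' @param seed Integer seed; required for reproducibility.
#' @return List with \code{grid}, \code{estimate}, \code{low}, \code{high}.
#' @export
bootstrap_proportion_ci <- function(ipd, statistic, grid, n_boot = 5000,
                                    level = 0.95, seed) {
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  est <- statistic(ipd, grid)
  arms <- split(seq_len(nrow(ipd)), ipd$arm)
  mat <- matrix(NA_real_, n_boot, length(grid))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(arms, function(ii) sample(ii, length(ii),
                                                   replace = TRUE)))
    mat[b, ] <- statistic(ipd[idx, , drop = FALSE], grid)
  }
  alpha <- (1 - level) / 2
  list(grid = grid, estimate = est,
       low = apply(mat, 2, stats::quantile, probs = alpha, na.rm = TRUE),
       high = apply(mat, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE))
}
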