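#' Two-arm trial design for synthetic data generation
#'
#' Describes the synthetic trial: per-arm sizes matching the CLL-8 trial
#' (408 treated, 409 control), uniform staggered accrual, administrative
#' cutoff at the end of the trial, and the generating illness-death
#' specification (default: the bundled Gompertz semi-Markov model).
#'
#' @param n_treated,n_control Patients per arm (defaults 408 and 409).
#' @param accrual Accrual window in years; entry times are uniform on
#'   \code{[0, accrual]} (default 1).
#' @param cutoff Trial end on the calendar clock, so follow-up is
#'   \code{cutoff - entry} (default 4, "up to 4 years" of follow-up).
#' @param spec Generating \code{\link{multistate_spec}}.
#' @param dropout_rate Optional exponential loss-to-follow-up rate per year
#'   (default 0 = administrative censoring only).
#' @return List of class \code{"trial_design"}.
#' @export
trial_design <- function(n_treated = 408, n_control = 409, accrual = 1,
                         cutoff = 4, spec = cll8_multistate_spec(),
                         dropout_rate = 0) {
  stopifnot(n_treated >= 1, n_control >= 1, cutoff > 0, accrual >= 0,
            dropout_rate >= 0)
  structure(list(n_treated = n_treated, n_control = n_control,
                 accrual = accrual, cutoff = cutoff, spec = spec,
                 dropout_rate = dropout_rate),
            class = "trial_design")
}

#' Simulate individual patient data from the illness-death model
#'
#' Latent transition times are drawn by inverse-cumulative-hazard sampling
#' per transition with the specification's clock conventions (competing
#' risks out of progression-free; clock reset on entry to progression by
#' default).  Follow-up is censored administratively at
#' \code{cutoff - entry}; events after censoring are unobserved, and a death
#' after an unobserved progression cannot itself be observed.
#'
#' @param design A \code{\link{trial_design}}.
#' @param seed Integer seed; required.
#' @return Wide IPD data frame: \code{id}, \code{arm} (1 treated /
#'   0 control), \code{t_progression}, \code{t_death} (\code{NA} when
#'   unobserved), \code{t_censor} (follow-up limit, years).
#' @export
simulate_trial <- function(design, seed) {
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  spec <- design$spec
  n <- design$n_treated + design$n_control
  arm <- rep(c(1, 0), c(design$n_treated, design$n_control))
  hr <- spec$hr
  mult <- function(i) ifelse(arm == 1, hr[i], 1)
  t12 <- hinvcumhaz(spec$models[[1]], stats::rexp(n) / mult(1))
  t13 <- hinvcumhaz(spec$models[[2]], stats::rexp(n) / mult(2))
  e23 <- stats::rexp(n) / mult(3)
  exit_pf <- pmin(t12, t13)
  progressed <- t12 < t13
  if (spec$clocks[3] == "reset") {
    t_death <- ifelse(progressed,
                      exit_pf + hinvcumhaz(spec$models[[3]], e23),
                      exit_pf)
  } else {
    Hentry <- hcumhaz(spec$models[[3]], exit_pf)
    t_death <- ifelse(progressed,
                      hinvcumhaz(spec$models[[3]], Hentry + e23),
                      exit_pf)
  }
  follow <- design$cutoff - stats::runif(n, 0, design$accrual)
  if (design$dropout_rate > 0)
    follow <- pmin(follow, stats::rexp(n, design$dropout_rate))
  obs_prog <- progressed & t12 <= follow
  obs_death <- t_death <= follow & (obs_prog | !progressed)
  data.frame(id = seq_len(n), arm = arm,
             t_progression = ifelse(obs_prog, t12, NA_real_),
             t_death = ifelse(obs_death, t_death, NA_real_),
             t_censor = follow)
}

#' Sample a censored dataset from a closed-form survival curve
#'
#' Draws i.i.d. event times by inversion from a \code{\link{hazard_model}},
#' optionally censored, for exercising Kaplan-Meier and tail-fitting code on
#' data whose true curve is known.
#'
#' @param model A \code{\link{hazard_model}} (no covariates).
#' @param n Sample size.
#' @param seed Integer seed; required.
#' @param censor Optional fixed censoring time, or a function \code{(n)}
#'   returning censoring times.
#' @return Data frame with \code{time} and \code{status}.
#' @export
km_fixture <- function(model, n, seed, censor = NULL) {
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  t <- hinvcumhaz(model, stats::rexp(n))
  if (is.null(censor)) return(data.frame(time = t, status = 1L))
  c_t <- if (is.function(censor)) censor(n) else rep(censor, n)
  data.frame(time = pmin(t, c_t), status = as.integer(t <= c_t))
}

#' Synthetic Gompertz-law life table
#'
#' Annual mortality probabilities rising exponentially with age,
#' \eqn{q(a) = \min\{q_0 e^{s(a - a_0)}, q_{max}\}}; a convenient synthetic
#' stand-in for a national life table when exercising the
#' max-with-background-mortality rule.
#'
#' @param ages Integer ages covered (default 40:100).
#' @param q0 Annual probability at the first age (default 0.002).
#' @param slope Log-linear increase per year of age (default 0.09).
#' @param qmax Probability cap (default 0.7).
#' @return Data frame with \code{age} and \code{annual_q}.
#' @export
life_table_fixture <- function(ages = 40:100, q0 = 0.002, slope = 0.09,
                               qmax = 0.7) {
  stopifnot(q0 > 0, q0 < 1, qmax <= 1)
  data.frame(age = ages,
             annual_q = pmin(q0 * exp(slope * (ages - ages[1])), qmax))
}

#' Expected event counts under a trial design
#'
#' Integrates the generating model to the expected numbers of observed
#' progressions, deaths after progression, and deaths without progression
#' per arm, by averaging state/event probabilities over the accrual-induced
#' follow-up distribution.  Used as the oracle when checking the simulator's
#' event counts.
#'
#' @param design A \code{\link{trial_design}}.
#' @param arm \code{"treated"} or \code{"control"}.
#' @param n_quad Quadrature points over the follow-up distribution.
#' @return Named vector: expected \code{progressions},
#'   \code{deaths_after_progression}, \code{deaths_without_progression}.
#' @export
expected_event_counts <- function(design, arm = c("control", "treated"),
                                  n_quad = 64) {
  arm <- match.arg(arm)
  spec <- design$spec
  treated <- arm == "treated"
  n <- if (treated) design$n_treated else design$n_control
  ## follow-up is uniform on [cutoff - accrual, cutoff]
  fu <- if (design$accrual > 0)
    seq(design$cutoff - design$accrual, design$cutoff,
        length.out = n_quad)
  else design$cutoff
  grid <- seq(0, design$cutoff, length.out = 2049)
  Spf <- exp(-(.trans_H(spec, 1, grid, treated) +
               .trans_H(spec, 2, grid, treated)))
  h12 <- .trans_h(spec, 1, grid, treated)
  h13 <- .trans_h(spec, 2, grid, treated)
  f12 <- Spf * h12; f13 <- Spf * h13
  f12[!is.finite(f12)] <- 0; f13[!is.finite(f13)] <- 0
  cum12 <- c(0, cumsum((f12[-1] + f12[-length(f12)]) / 2 * diff(grid)))
  cum13 <- c(0, cumsum((f13[-1] + f13[-length(f13)]) / 2 * diff(grid)))
  P12 <- function(t) stats::approx(grid, cum12, xout = t)$y
  P13 <- function(t) stats::approx(grid, cum13, xout = t)$y
  ## deaths after progression by c: integrate progression density times
  ## the probability the reset-clock sojourn ends before follow-up
  H23 <- function(s) .trans_H(spec, 3, pmax(s, 0), treated)
  d_after <- vapply(fu, function(cc) {
    ii <- grid <= cc
    f <- f12[ii] * (1 - exp(-H23(cc - grid[ii])))
    sum((f[-1] + f[-length(f)]) / 2 * diff(grid[ii]))
  }, numeric(1))
  counts <- c(progressions = mean(P12(fu)),
              deaths_after_progression = mean(d_after),
              deaths_without_progression = mean(P13(fu)))
  n * counts
}
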