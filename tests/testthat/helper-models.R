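# shared model constructors and small oracles

fc_os_exponential <- function()
  hazard_model("exponential", c(log_scale = 2.753),
               coefficients = c(treat = -0.284))

fc_os_tail <- function()
  hazard_model("weibull_ph", c(log_rate = -4.377, shape = 2.257))

pfs_weibull <- function()
  hazard_model("weibull", c(log_scale = 1.237, log_shape = 0.310),
               coefficients = c(treat = -0.519))

gompertz_12 <- function() hazard_model("gompertz", c(shape = 0.474,
                                                     log_rate = -2.187))
gompertz_13 <- function() hazard_model("gompertz", c(shape = -0.487,
                                                     log_rate = -2.825))
gompertz_23 <- function() hazard_model("gompertz", c(shape = 0.174,
                                                     log_rate = -1.627))

## brute-force Aalen-Johansen on a tiny dataset (events before censorings at
## ties, like the estimator under test)
aj_oracle <- function(time, cause) {
  ord <- order(time, cause == 0)
  time <- time[ord]; cause <- cause[ord]
  ut <- sort(unique(time[cause != 0]))
  causes <- sort(unique(cause[cause != 0]))
  S <- 1
  ci <- matrix(0, length(ut), length(causes),
               dimnames = list(NULL, as.character(causes)))
  km <- numeric(length(ut))
  for (i in seq_along(ut)) {
    tt <- ut[i]
    n_at_risk <- sum(time >= tt)
    if (i > 1) ci[i, ] <- ci[i - 1, ]
    for (j in seq_along(causes)) {
      d <- sum(time == tt & cause == causes[j])
      ci[i, j] <- ci[i, j] + S * d / n_at_risk
    }
    d_all <- sum(time == tt & cause != 0)
    S <- S * (1 - d_all / n_at_risk)
    km[i] <- S
  }
  list(time = ut, cuminc = ci, km = km)
}

## closed-form three-state occupancy under constant hazards (clock convention
## irrelevant for exponentials)
constant_hazard_occupancy <- function(t, l12, l13, l23) {
  pf <- exp(-(l12 + l13) * t)
  prog <- if (abs(l12 + l13 - l23) < 1e-12) l12 * t * exp(-l23 * t)
          else l12 * (exp(-l23 * t) - exp(-(l12 + l13) * t)) /
               (l12 + l13 - l23)
  list(pf = pf, prog = prog, dead = 1 - pf - prog)
}
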