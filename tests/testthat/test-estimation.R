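test_that("Kaplan-Meier matches hand product-limit results", {
  km <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_step(km, 1.5), 2 / 3)
  expect_equal(km_step(km, 3), 0)
  ## all censored
  km2 <- km_fit(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  ## single death
  km3 <- km_fit(2, 1)
  expect_equal(km3$surv, 0)
  ## ties: deaths before censorings at equal times
  km4 <- km_fit(c(1, 1, 2), c(1, 0, 1))
  expect_equal(km4$surv[km4$time == 1], 2 / 3)
  expect_error(km_fit(numeric(0), numeric(0)), "empty")
})

test_that("KM equals empirical survival without censoring", {
  set.seed(3)
  t <- rexp(200, 0.4)
  km <- km_fit(t, rep(1, 200))
  emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("restricted mean is the area under the KM step function", {
  km <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_restricted_mean(km, 3), 1 + 2 * (2 / 3),
               tolerance = 1e-12)
  expect_equal(km_restricted_mean(km_fit(c(5, 6), c(0, 0)), 2), 2)
  km5 <- km_fit(c(1, 1), c(1, 0))   # S = 0.5 on [1, ...
  expect_equal(km_restricted_mean(km5, 2), 1.5)
})

test_that("rate <-> probability conversion and the 0.0405 worked example", {
  expect_equal(rate_to_probability(1 / 24.1791), 0.0405, tolerance = 1e-3)
  expect_equal(rate_to_probability(0), 0)
  expect_equal(probability_to_rate(rate_to_probability(0.3)), 0.3,
               tolerance = 1e-12)
  expect_error(probability_to_rate(1), "in \\[0,1\\)")
})

test_that("cumulative incidence matches the brute-force Aalen-Johansen", {
  time <- c(1, 1, 2, 3, 4)
  cause <- c(1, 2, 1, 0, 2)
  got <- cuminc_fit(time, cause)
  want <- aj_oracle(time, cause)
  expect_equal(got$time[got$time %in% want$time], want$time)
  keep <- got$time %in% want$time
  expect_equal(unname(got$cuminc[keep, "1"]), unname(want$cuminc[, "1"]),
               tolerance = 1e-12)
  expect_equal(unname(got$cuminc[keep, "2"]), unname(want$cuminc[, "2"]),
               tolerance = 1e-12)
  ## incidences + all-cause survival sum to one
  expect_equal(rowSums(got$cuminc) + got$km, rep(1, length(got$time)),
               tolerance = 1e-12)
  ## single event type degenerates to 1 - KM
  g1 <- cuminc_fit(c(1, 2, 3), c(1, 0, 1))
  km <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(unname(g1$cuminc[g1$time %in% km$time, "1"]),
               1 - km$surv, tolerance = 1e-12)
  ## no events
  g0 <- cuminc_fit(c(1, 2), c(0, 0))
  expect_true(all(g0$cuminc == 0))
})

test_that("exponential MLE reproduces the events/exposure closed form", {
  set.seed(11)
  n <- 5000
  t <- rexp(n, 0.5)
  rec <- data.frame(tstart = 0, tstop = t, status = 1L)
  fit <- fit_parametric(rec, "exponential")
  rate_hat <- exp(-fit$params[1])
  expect_equal(rate_hat, sum(rec$status) / sum(rec$tstop),
               tolerance = 1e-6)
  expect_lt(abs(rate_hat - 0.5) / (rate_hat / sqrt(n)), 3)  # within 3 SE
})

test_that("Weibull fit on shape-1 data covers shape 1", {
  set.seed(12)
  t <- rexp(800, 0.3)
  rec <- data.frame(tstart = 0, tstop = t, status = 1L)
  fit <- fit_parametric(rec, "weibull")
  shape <- exp(fit$params[2])
  se_logshape <- fit$se[["p2"]]
  expect_lt(abs(fit$params[2]) / se_logshape, 3)   # log-shape CI covers 0
  expect_gt(shape, 0.8); expect_lt(shape, 1.2)
})

test_that("Gompertz parameters are recovered from censored data", {
  set.seed(13)
  m <- gompertz_12()
  t <- hinvcumhaz(m, rexp(2000))
  rec <- data.frame(tstart = 0, tstop = pmin(t, 4),
                    status = as.integer(t <= 4))
  fit <- fit_parametric(rec, "gompertz")
  expect_lt(abs(fit$params[1] - 0.474) / fit$se[["p1"]], 3)
  expect_lt(abs(fit$params[2] - (-2.187)) / fit$se[["p2"]], 3)
})

test_that("MLE agrees with the flexsurv reference fitter", {
  set.seed(14)
  t <- hinvcumhaz(hazard_model("weibull", c(0.6, 0.3)), rexp(600))
  x <- rbinom(600, 1, 0.5)
  t <- t * exp(-0.4 * x)^(1 / exp(0.3))   # PH effect on a Weibull
  rec <- data.frame(tstart = 0, tstop = pmin(t, 6),
                    status = as.integer(t <= 6), treat = x)
  fit <- fit_parametric(rec, "weibull", "treat")
  ref <- flexsurv::flexsurvreg(survival::Surv(tstop, status) ~ treat,
                               data = rec, dist = "weibullPH")
  ## translate: weibullPH scale = exp(-shape * log_scale_ours)
  expect_equal(unname(fit$coefficients["treat"]),
               unname(ref$res["treat", "est"]), tolerance = 1e-3)
  expect_equal(exp(fit$params[2]), unname(ref$res["shape", "est"]),
               tolerance = 1e-3)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)
})

test_that("likelihood factorizes over record splits (left truncation)", {
  set.seed(15)
  m <- gompertz_12()
  t <- hinvcumhaz(m, rexp(400))
  rec <- data.frame(tstart = 0, tstop = pmin(t, 5),
                    status = as.integer(t <= 5))
  ## split every record at an arbitrary interior time
  cut <- rec$tstop * 0.37
  rec_split <- rbind(
    data.frame(tstart = 0, tstop = cut, status = 0L),
    data.frame(tstart = cut, tstop = rec$tstop, status = rec$status))
  f1 <- fit_parametric(rec, "gompertz")
  f2 <- fit_parametric(rec_split, "gompertz")
  expect_equal(f1$params, f2$params, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("AIC formula and its time-scale dependence", {
  fake <- structure(list(loglik = -100, params = 1:2,
                         coefficients = c(a = 0.1)),
                    class = c("transition_fit", "hazard_model"))
  expect_equal(aic(fake), 206)
  ## Delta-AIC between families depends on the time unit (Jacobian)
  set.seed(16)
  t <- rexp(300, 0.8)
  rec_y <- data.frame(tstart = 0, tstop = t, status = 1L)
  rec_m <- data.frame(tstart = 0, tstop = t * 12, status = 1L)
  d_y <- aic(fit_parametric(rec_y, "weibull")) -
    aic(fit_parametric(rec_y, "lognormal"))
  d_m <- aic(fit_parametric(rec_m, "weibull")) -
    aic(fit_parametric(rec_m, "lognormal"))
  expect_equal(d_y, d_m, tolerance = 1e-4)  # Delta-AIC is scale-invariant...
  a_y <- aic(fit_parametric(rec_y, "weibull"))
  a_m <- aic(fit_parametric(rec_m, "weibull"))
  expect_gt(abs(a_y - a_m), 1)              # ...but absolute AIC is not
})

test_that("Cox-Snell residuals of a correct model are unit exponential", {
  set.seed(17)
  t <- rexp(1500, 0.6)
  rec <- data.frame(tstart = 0, tstop = pmin(t, 4),
                    status = as.integer(t <= 4))
  fit <- fit_parametric(rec, "exponential")
  rs <- cox_snell(fit, rec)
  km <- km_fit(rs$residual, rs$status)
  expect_lt(max(abs(km$surv - exp(-km$time))), 0.05)
})

test_that("state-arrival check holds its size under the Markov null and
           detects a true arrival effect", {
  ## null: clock-forward (Markov) transition out of progression
  sim_records <- function(n, beta_arr, seed) {
    set.seed(seed)
    arrival <- runif(n, 0.2, 3)
    treat <- rbinom(n, 1, 0.5)
    rate <- 0.4 * exp(0.3 * treat + beta_arr * arrival)
    ## clock-forward constant hazard after arrival
    death <- arrival + rexp(n, rate)
    cens <- arrival + runif(n, 1, 6)
    data.frame(tstart = arrival, tstop = pmin(death, cens),
               status = as.integer(death <= cens), treat = treat,
               arrival = arrival)
  }
  pvals <- vapply(1:100, function(i)
    state_arrival_check(sim_records(150, 0, i))$p, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.12)        # near-nominal size
  rej <- vapply(1:25, function(i)
    state_arrival_check(sim_records(1000, 0.5, 1000 + i))$p < 0.05,
    logical(1))
  expect_gt(mean(rej), 0.8)                  # power at beta = 0.5
  ## degenerate arrival covariate
  bad <- sim_records(50, 0, 1)
  bad$arrival <- 1
  expect_error(state_arrival_check(bad), "constant")
})

test_that("bootstrap band is sane and attains near-nominal coverage", {
  prop_in_prog <- function(ipd, grid) {
    vapply(grid, function(t) {
      prog <- !is.na(ipd$t_progression) & ipd$t_progression <= t
      alive <- is.na(ipd$t_death) | ipd$t_death > t
      mean(prog & alive)
    }, numeric(1))
  }
  design <- trial_design(n_treated = 60, n_control = 60)
  ipd <- simulate_trial(design, seed = 21)
  band <- bootstrap_proportion_ci(ipd, prop_in_prog, grid = c(1, 2, 3),
                                  n_boot = 300, seed = 1)
  expect_true(all(band$low <= band$estimate + 1e-12))
  expect_true(all(band$high >= band$estimate - 1e-12))
  ## degenerate data: identical subjects give a zero-width band
  dupe <- ipd[rep(1, 40), ]
  dupe$id <- seq_len(40)
  band0 <- bootstrap_proportion_ci(dupe, prop_in_prog, grid = c(1, 2),
                                   n_boot = 50, seed = 2)
  expect_equal(band0$low, band0$high)
  expect_error(bootstrap_proportion_ci(ipd, prop_in_prog, grid = 1),
               "seed")
  ## coverage of the generating model's occupancy at t = 2
  truth <- occupancy_numeric(cll8_multistate_spec(), treated = FALSE,
                             horizon = 3, step = 1 / 12)
  p_true <- truth$prog[which.min(abs(truth$time - 2))]
  hits <- vapply(1:40, function(i) {
    ipd_i <- simulate_trial(trial_design(n_treated = 2, n_control = 120),
                            seed = 100 + i)
    ipd_i <- ipd_i[ipd_i$arm == 0, ]
    b <- bootstrap_proportion_ci(ipd_i, prop_in_prog, grid = 2,
                                 n_boot = 200, seed = i)
    b$low <= p_true && p_true <= b$high
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("IPD conversion produces consistent transition records", {
  ipd <- data.frame(id = 1:4, arm = c(0, 0, 1, 1),
                    t_progression = c(1, NA, 2, NA),
                    t_death = c(2.5, 1.5, NA, NA),
                    t_censor = c(4, 4, 3.5, 3))
  rec <- ipd_to_records(ipd, clock23 = "reset")
  r1 <- rec[rec$trans == 1, ]
  expect_equal(r1$tstop, c(1, 1.5, 2, 3))
  expect_equal(r1$status, c(1L, 0L, 1L, 0L))
  r2 <- rec[rec$trans == 2, ]
  expect_equal(r2$status, c(0L, 1L, 0L, 0L))
  r3 <- rec[rec$trans == 3, ]
  expect_equal(nrow(r3), 2)
  expect_equal(r3$tstart, c(0, 0))                  # reset clock
  expect_equal(r3$tstop, c(1.5, 1.5))
  expect_equal(r3$status, c(1L, 0L))
  expect_equal(r3$arrival, c(1, 2))
  rf <- ipd_to_records(ipd, clock23 = "forward")
  r3f <- rf[rf$trans == 3, ]
  expect_equal(r3f$tstart, c(1, 2))
  expect_equal(r3f$tstop, c(2.5, 3.5))
})
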