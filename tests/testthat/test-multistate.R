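test_that("the coarse monthly grid fails the increment-below-one check
           after nine years and the refined grid passes", {
  spec <- cll8_multistate_spec()
  ## coarse-only grid: the accelerating PF->progression Gompertz hazard
  ## eventually produces increments above one
  coarse <- build_hazard_grid(spec, refine_after = 15, validate = FALSE)
  i14 <- which(abs(coarse$grid - 14) < 1e-9)
  expect_gt(coarse$dH[i14, "pf_prog"], 1)          # ~7 over one month at 14y
  expect_false(coarse$ok)
  expect_error(build_hazard_grid(spec, refine_after = 15), "refine")
  ## offending increments only appear after 9 years
  bad <- which(coarse$dH >= 1, arr.ind = TRUE)
  expect_gt(min(coarse$grid[bad[, 1]]), 9)
  ## the refined grid (1/144 beyond 9 years) passes everywhere
  fine <- build_hazard_grid(spec)
  expect_true(fine$ok)
  expect_true(all(fine$dH < 1))
})

test_that("hazard-increment shapes follow the transition hazards", {
  ## constant hazard: constant increments
  ex <- multistate_spec(list(hazard_model("exponential", -log(0.1)),
                             hazard_model("exponential", -log(0.1)),
                             hazard_model("exponential", -log(0.1))))
  g <- build_hazard_grid(ex, refine_after = 15)
  expect_equal(g$dH[, 1], rep(0.1 / 12, nrow(g$dH)), tolerance = 1e-12)
  ## negative Gompertz shape: decreasing increments
  spec <- cll8_multistate_spec()
  g2 <- build_hazard_grid(spec)
  expect_true(all(diff(g2$dH[, "pf_death"]) <= 1e-14))
})

test_that("path simulation matches the closed-form constant-hazard
           occupancy", {
  l <- c(0.2, 0.05, 0.4)
  spec <- multistate_spec(lapply(-log(l), function(s)
    hazard_model("exponential", s)))
  tr <- simulate_paths(spec, n_paths = 50000, seed = 101, horizon = 10)
  oracle <- constant_hazard_occupancy(tr$time, l[1], l[2], l[3])
  for (st in c("pf", "prog", "dead")) {
    dev <- abs(tr[[st]] - oracle[[st]])
    ## 4-SE band: the max over ~180 grid points of a 3-SE pointwise band
    ## is exceeded by chance alone
    band <- 4 * tr[[paste0("se_", st)]] + 1e-6
    expect_true(all(dev <= band))
  }
})

test_that("zero progression hazard degenerates to a single survival curve", {
  spec <- multistate_spec(list(
    hazard_model("exponential", c(log_scale = 40)),    # rate ~ 0
    gompertz_13(),
    gompertz_23()))
  tr <- simulate_paths(spec, n_paths = 20000, seed = 102)
  expect_true(all(tr$prog == 0))
  s13 <- hsurv(gompertz_13(), tr$time)
  expect_true(all(abs(tr$pf - s13) <= 4 * tr$se_pf + 1e-6))
})

test_that("grid and exact sampling mechanisms agree", {
  spec <- cll8_multistate_spec()
  a <- simulate_paths(spec, n_paths = 50000, seed = 103, method = "exact")
  b <- simulate_paths(spec, n_paths = 50000, seed = 104, method = "grid")
  for (st in c("pf", "prog", "dead")) {
    dev <- abs(a[[st]] - b[[st]])
    ## the increment-as-probability scheme has O(dH) bias at the monthly
    ## step (~0.01 in occupancy); the refinement check below shows it shrink
    band <- 3 * sqrt(a[[paste0("se_", st)]]^2 +
                     b[[paste0("se_", st)]]^2) + 0.015
    expect_true(all(dev <= band))
  }
  ## grid-method bias shrinks as the step is refined
  num <- occupancy_numeric(spec)
  coarse <- simulate_paths(spec, n_paths = 50000, seed = 105,
                           method = "grid", refine_after = 15)
  fine <- simulate_paths(spec, n_paths = 50000, seed = 105,
                         method = "grid", refine_after = 0,
                         refine_step = 1 / 144)
  expect_lt(max(abs(fine$prog - num$prog)), max(abs(coarse$prog - num$prog)))
})

test_that("simulator agrees with the deterministic convolution oracle on
           both arms", {
  spec <- cll8_multistate_spec()
  for (treated in c(FALSE, TRUE)) {
    sim <- simulate_paths(spec, treated = treated, n_paths = 50000,
                          seed = 110 + treated)
    num <- occupancy_numeric(spec, treated = treated)
    for (st in c("pf", "prog", "dead")) {
      dev <- abs(sim[[st]] - num[[st]])
      band <- 4 * sim[[paste0("se_", st)]] + 5e-4   # + quadrature error
      expect_true(all(dev <= band))
    }
  }
})

test_that("numeric occupancy reproduces the published anchor and its
           degenerate cases", {
  spec <- cll8_multistate_spec()
  num <- occupancy_numeric(spec)
  i4 <- which(num$time == 4)
  expect_equal(num$pf[i4], 0.2358, tolerance = 1e-3)
  expect_equal(num$pf[1], 1); expect_equal(num$prog[1], 0)
  expect_equal(num$dead[1], 0)
  ## zero progression-to-death hazard: progression occupancy equals the
  ## cause-specific cumulative incidence of the progression transition
  spec0 <- multistate_spec(list(gompertz_12(), gompertz_13(),
                                hazard_model("exponential",
                                             c(log_scale = 40))))
  num0 <- occupancy_numeric(spec0)
  u <- seq(0, 4, by = 1 / 1200)
  f <- exp(-(hcumhaz(gompertz_12(), u) + hcumhaz(gompertz_13(), u))) *
    hhaz(gompertz_12(), u)
  ci4 <- sum((f[-1] + f[-length(f)]) / 2) * (1 / 1200)
  expect_equal(num0$prog[which(num0$time == 4)], ci4, tolerance = 1e-4)
})

test_that("treatment scaling behaves as proportional hazards", {
  spec <- cll8_multistate_spec()
  ## unit hazard ratios change nothing
  null <- multistate_spec(spec$models, spec$clocks, hr = c(1, 1, 1))
  a <- occupancy_numeric(null, treated = TRUE)
  b <- occupancy_numeric(null, treated = FALSE)
  expect_equal(a$prog, b$prog, tolerance = 1e-12)
  ## the published ratios: exp(0.342) = 1.408 for progression -> death
  expect_equal(exp(0.342), 1.408, tolerance = 1e-3)
  ## doubling a hazard squares the latent-time survival
  scaled <- apply_treatment(spec, c(2, 1, 1))
  t <- c(1, 3, 7)
  expect_equal(hsurv(scaled$models[[1]], t, c(.treat_scale = 1)),
               hsurv(spec$models[[1]], t)^2, tolerance = 1e-12)
})

test_that("simulation is reproducible and refuses to run unseeded", {
  spec <- cll8_multistate_spec()
  a <- simulate_paths(spec, n_paths = 2000, seed = 7)
  b <- simulate_paths(spec, n_paths = 2000, seed = 7)
  expect_identical(a$pf, b$pf)
  expect_error(simulate_paths(spec, n_paths = 10), "seed")
})

test_that("transition fits on synthetic trial data recover the generating
           parameters within three standard errors", {
  design <- trial_design(n_treated = 2000, n_control = 2000, cutoff = 6)
  ipd <- simulate_trial(design, seed = 120)
  spec_hat <- fit_multistate(ipd)
  fits <- attr(spec_hat, "fits")
  gen <- cll8_multistate_spec()
  truth <- list(c(0.474, -2.187, log(0.572)),
                c(-0.487, -2.825, log(0.710)),
                c(0.174, -1.627, log(1.408)))
  for (i in 1:3) {
    est <- c(fits[[i]]$params, fits[[i]]$coefficients[["treat"]])
    se <- unname(fits[[i]]$se)
    expect_true(all(abs(est - truth[[i]]) / se < 3),
                info = paste("transition", i))
  }
  ## occupancy from the fitted spec tracks the generating spec
  occ_hat <- occupancy_numeric(spec_hat, horizon = 6)
  occ_gen <- occupancy_numeric(gen, horizon = 6)
  expect_lt(max(abs(occ_hat$prog - occ_gen$prog)), 0.03)
})
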