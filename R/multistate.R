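#' Illness-death multi-state model specification
#'
#' Three states (1 = progression-free, 2 = progression, 3 = death) and three
#' transitions (1: PF to progression, 2: PF to death, 3: progression to
#' death), each with a parametric hazard model and a clock convention:
#' \code{"forward"} (hazard indexed by study time) or \code{"reset"} (time
#' since entering the originating state; semi-Markov).  Transitions out of
#' the initial state start at study time zero, so their two conventions
#' coincide; the convention matters for progression to death.
#'
#' Treatment enters as a per-transition hazard ratio, kept separate from the
#' fitted coefficients so that published hazard ratios can be used directly
#' when a source table is internally inconsistent.
#'
#' @param models List of three \code{\link{hazard_model}}s, in transition
#'   order (PF-progression, PF-death, progression-death).
#' @param clocks Character vector of three clock conventions.
#' @param hr Numeric vector of three treatment hazard ratios (treated vs
#'   control), applied by \code{\link{apply_treatment}}; default all 1.
#' @return Object of class \code{"multistate_spec"}.
#' @export
multistate_spec <- function(models,
                            clocks = c("forward", "forward", "reset"),
                            hr = c(1, 1, 1)) {
  stopifnot(length(models) == 3, length(clocks) == 3, length(hr) == 3,
            all(hr > 0),
            all(vapply(models, inherits, logical(1), "hazard_model")),
            all(clocks %in% c("forward", "reset")))
  structure(list(models = models, clocks = clocks, hr = hr),
            class = "multistate_spec")
}

#' @export
print.multistate_spec <- function(x, ...) {
  nm <- c("PF -> progression", "PF -> death", "progression -> death")
  cat("Illness-death multi-state model\n")
  for (i in 1:3)
    cat(sprintf("  %-22s %-11s clock-%s  HR %.3f\n", nm[i],
                x$models[[i]]$family, x$clocks[i], x$hr[i]))
  invisible(x)
}

#' Bundled CLL-8 semi-Markov specification
#'
#' Loads the Gompertz transition models published for the CLL-8 trial.
#' Treatment hazard ratios default to the printed values; set
#' \code{treatment_effect = "coefficient"} to use \eqn{\exp(\beta)} of the
#' printed coefficients instead (the published table is inconsistent for the
#' progression transition).
#'
#' @param path Optional alternative YAML fixture path.
#' @param treatment_effect \code{"hr"} (printed hazard ratios, default) or
#'   \code{"coefficient"}.
#' @return A \code{\link{multistate_spec}} for the control (FC) arm, with
#'   treatment hazard ratios attached.
#' @export
cll8_multistate_spec <- function(path = NULL,
                                 treatment_effect = c("hr", "coefficient")) {
  treatment_effect <- match.arg(treatment_effect)
  if (is.null(path))
    path <- system.file("extdata", "cll8_multistate.yaml",
                        package = "idmcea", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  tr <- y$transitions[c("pf_to_prog", "pf_to_death", "prog_to_death")]
  models <- lapply(tr, function(b) hazard_model(b$family, unlist(b$params)))
  hr <- vapply(tr, function(b)
    if (treatment_effect == "hr") b$hr else exp(b$coefficient), numeric(1))
  multistate_spec(unname(models),
                  clocks = vapply(tr, `[[`, character(1), "clock"),
                  hr = unname(hr))
}

#' Scale transition hazards by treatment hazard ratios
#'
#' Proportional-hazards scaling of each transition's hazard; returns a new
#' specification whose baseline now describes the treated arm.
#'
#' @param spec A \code{\link{multistate_spec}}.
#' @param hr_map Hazard ratios per transition (defaults to \code{spec$hr}).
#' @return A \code{multistate_spec} with unit hazard ratios.
#' @export
apply_treatment <- function(spec, hr_map = spec$hr) {
  stopifnot(length(hr_map) == 3, all(hr_map > 0))
  models <- lapply(1:3, function(i) {
    m <- spec$models[[i]]
    hm <- hazard_model(m$family, m$params,
                       coefficients = c(.treat_scale = log(hr_map[i])),
                       effect_type = "PH")
    hm
  })
  out <- multistate_spec(models, spec$clocks, hr = c(1, 1, 1))
  attr(out, "scaled") <- TRUE
  out
}

## per-transition H(t) for an arm: arm "treated" applies spec$hr[i]
.trans_H <- function(spec, i, t, treated = FALSE) {
  mult <- if (treated) spec$hr[i] else 1
  mult * hcumhaz(spec$models[[i]], t)
}
.trans_h <- function(spec, i, t, treated = FALSE) {
  mult <- if (treated) spec$hr[i] else 1
  mult * hhaz(spec$models[[i]], t)
}

#' Cumulative-hazard increments on the refined grid
#'
#' Builds the internal evaluation grid (coarse step to \code{refine_after},
#' fine step beyond) and the per-transition cumulative-hazard increments on
#' it, validating the requirement that every increment is below one (needed
#' for increments to be usable as transition probabilities).  For the
#' clock-reset transition the increments are computed on the sojourn-time
#' clock from zero.
#'
#' @param spec A \code{\link{multistate_spec}}.
#' @param treated Apply the treatment hazard ratios?
#' @param horizon Years (default 15).
#' @param step Coarse step (default 1/12).
#' @param refine_after Time after which the fine step is used (default 9);
#'   set to \code{horizon} to disable refinement.
#' @param refine_step Fine step (default 1/144).
#' @return List with \code{grid}, matrix \code{dH} (one column per
#'   transition), and \code{ok}.  When any increment is at or above one the
#'   function signals an error naming the first offending interval unless
#'   \code{validate = FALSE}.
#' @param validate Signal an error on increments at or above one?
#' @export
build_hazard_grid <- function(spec, treated = FALSE, horizon = 15,
                              step = 1 / 12, refine_after = 9,
                              refine_step = 1 / 144, validate = TRUE) {
  grid <- refined_grid(horizon, step, refine_after, refine_step)
  dH <- vapply(1:3, function(i) {
    H <- .trans_H(spec, i, grid, treated)
    diff(H)
  }, numeric(length(grid) - 1))
  colnames(dH) <- c("pf_prog", "pf_death", "prog_death")
  bad <- which(dH >= 1, arr.ind = TRUE)
  if (nrow(bad) > 0 && validate) {
    j <- bad[1, 1]
    stop(sprintf(paste0("cumulative-hazard increment %.3g >= 1 on ",
                        "[%.4f, %.4f] for transition %s; refine the grid"),
                 dH[bad[1, 1], bad[1, 2]], grid[j], grid[j + 1],
                 colnames(dH)[bad[1, 2]]))
  }
  list(grid = grid, dH = dH, ok = nrow(bad) == 0)
}

#' @rdname build_hazard_grid
#' @export
refined_grid <- function(horizon = 15, step = 1 / 12, refine_after = 9,
                         refine_step = 1 / 144) {
  if (refine_after >= horizon) return(seq(0, horizon, by = step))
  c(seq(0, refine_after, by = step),
    seq(refine_after + refine_step, horizon, by = refine_step))
}

#' Simulate sample paths through the illness-death model
#'
#' Draws individual paths and reports the fraction of paths in each state at
#' every reporting time, with binomial Monte-Carlo standard errors.
#'
#' Two sampling mechanisms are provided.  \code{"exact"} samples each
#' latent transition time by inversion, \eqn{T = H^{-1}(-\log U)} on the
#' transition's clock, takes the minimum of the two competing risks out of
#' progression-free, and (for paths that progress) adds a clock-reset
#' progression-to-death sojourn.  \code{"grid"} walks the refined grid,
#' treating each transition's cumulative-hazard increment over a step as its
#' event probability (competing events selected proportionally), which is
#' the mechanism implied by the below-one increment requirement.
#'
#' @param spec A \code{\link{multistate_spec}}.
#' @param treated Apply the treatment hazard ratios?
#' @param n_paths Number of simulated paths (default 5000).
#' @param seed Integer seed; required.
#' @param method \code{"exact"} (default) or \code{"grid"}.
#' @param horizon,step Reporting grid settings (default 15 years, 1/12).
#' @param refine_after,refine_step Internal grid refinement for the
#'   \code{"grid"} method (defaults 9 years, 1/144).
#' @return An \code{\link{occupancy_trace}} on the reporting grid with
#'   Monte-Carlo standard errors; the simulated event times are attached as
#'   attribute \code{"paths"} (a data frame with \code{t_prog},
#'   \code{t_death}, possibly infinite).
#' @export
simulate_paths <- function(spec, treated = FALSE, n_paths = 5000, seed,
                           method = c("exact", "grid"), horizon = 15,
                           step = 1 / 12, refine_after = 9,
                           refine_step = 1 / 144) {
  if (missing(seed)) stop("'seed' is required for reproducible simulation")
  method <- match.arg(method)
  set.seed(seed)
  hr <- if (treated) spec$hr else c(1, 1, 1)

  if (method == "exact") {
    e12 <- stats::rexp(n_paths) / hr[1]
    e13 <- stats::rexp(n_paths) / hr[2]
    e23 <- stats::rexp(n_paths) / hr[3]
    t12 <- hinvcumhaz(spec$models[[1]], e12)
    t13 <- hinvcumhaz(spec$models[[2]], e13)
    exit_pf <- pmin(t12, t13)
    progressed <- t12 < t13
    s23 <- hinvcumhaz(spec$models[[3]], e23)   # sojourn on reset clock
    t_prog <- ifelse(progressed, exit_pf, Inf)
    t_death <- ifelse(progressed,
                      if (spec$clocks[3] == "reset") exit_pf + s23
                      else pmax(s23, exit_pf),   # forward clock, delayed entry
                      exit_pf)
    if (spec$clocks[3] == "forward" && any(progressed)) {
      ## forward clock with delayed entry: conditional inversion
      ## H23(T) = H23(t_prog) + E  =>  T = H23^{-1}(H23(t_prog) + E)
      ip <- which(progressed)
      Hentry <- hr[3] * hcumhaz(spec$models[[3]], exit_pf[ip])
      t_death[ip] <- hinvcumhaz(spec$models[[3]],
                                (Hentry + stats::rexp(length(ip))) / hr[3])
    }
  } else {
    g <- build_hazard_grid(spec, treated = FALSE, horizon = horizon,
                           step = step, refine_after = refine_after,
                           refine_step = refine_step, validate = FALSE)
    grid <- g$grid
    nstep <- length(grid) - 1
    ## clock-reset transition: cumulative hazard evaluated per-path below
    state <- rep(1L, n_paths)           # 1 PF, 2 prog, 3 dead
    t_prog <- rep(Inf, n_paths); t_death <- rep(Inf, n_paths)
    entry <- rep(NA_real_, n_paths)     # progression entry time
    for (s in seq_len(nstep)) {
      t0 <- grid[s]; t1 <- grid[s + 1]
      in_pf <- which(state == 1L)
      in_prog <- which(state == 2L)   # before this step's new entrants
      if (length(in_pf)) {
        p12 <- hr[1] * g$dH[s, 1]
        p13 <- hr[2] * g$dH[s, 2]
        if (p12 + p13 >= 1)
          stop("competing exit probability >= 1 at t = ", t0,
               "; refine the grid")
        u <- stats::runif(length(in_pf))
        ev12 <- u < p12
        ev13 <- !ev12 & u < p12 + p13
        if (any(ev12)) {
          idx <- in_pf[ev12]
          state[idx] <- 2L; t_prog[idx] <- t1; entry[idx] <- t1
        }
        if (any(ev13)) {
          idx <- in_pf[ev13]
          state[idx] <- 3L; t_death[idx] <- t1
        }
      }
      if (length(in_prog)) {
        m23 <- spec$models[[3]]
        if (spec$clocks[3] == "reset") {
          s0 <- t0 - entry[in_prog]; s1 <- t1 - entry[in_prog]
          p23 <- hr[3] * (hcumhaz(m23, s1) - hcumhaz(m23, s0))
        } else {
          p23 <- rep(hr[3] * (hcumhaz(m23, t1) - hcumhaz(m23, t0)),
                     length(in_prog))
        }
        dies <- stats::runif(length(in_prog)) < pmin(p23, 1)
        if (any(dies)) {
          idx <- in_prog[dies]
          state[idx] <- 3L; t_death[idx] <- t1
        }
      }
    }
  }

  report <- seq(0, horizon, by = step)
  occ <- path_occupancy(t_prog, t_death, report)
  occ$trace <- structure(occ$trace, paths = data.frame(t_prog = t_prog,
                                                       t_death = t_death))
  occ$trace
}

## occupancy (+ binomial MC SEs) of simulated paths at reporting times
path_occupancy <- function(t_prog, t_death, report) {
  n <- length(t_death)
  pf <- vapply(report, function(t) mean(t_prog > t & t_death > t), numeric(1))
  prog <- vapply(report, function(t) mean(t_prog <= t & t_death > t),
                 numeric(1))
  dead <- 1 - pf - prog
  se <- function(p) sqrt(pmax(p * (1 - p), 0) / n)
  trace <- occupancy_trace(report, pf, prog, dead,
                           mc_se = list(pf = se(pf), prog = se(prog),
                                        dead = se(dead)))
  list(trace = trace)
}

#' Deterministic state occupancy by semi-Markov convolution
#'
#' Computes occupancy without simulation:
#' \deqn{P_{PF}(t) = \exp\{-H_{12}(t) - H_{13}(t)\}}
#' \deqn{P_{Prog}(t) = \int_0^t P_{PF}(u)\, h_{12}(u)\,
#'   e^{-H_{23}(t-u)}\, du}
#' (clock-reset form; for a clock-forward progression-to-death transition the
#' survivor factor is \eqn{\exp\{-(H_{23}(t) - H_{23}(u))\}}), with
#' \eqn{P_{Dead} = 1 - P_{PF} - P_{Prog}}.  The convolution integral is
#' evaluated by the composite trapezoidal rule on a fine uniform grid.
#'
#' @param spec A \code{\link{multistate_spec}}.
#' @param treated Apply the treatment hazard ratios?
#' @param horizon Years (default 15).
#' @param step Reporting step (default 1/12).
#' @param fine Integration substeps per reporting step (default 4).
#' @return An \code{\link{occupancy_trace}} on the reporting grid.
#' @export
occupancy_numeric <- function(spec, treated = FALSE, horizon = 15,
                              step = 1 / 12, fine = 4) {
  report <- seq(0, horizon, by = step)
  u <- seq(0, horizon, by = step / fine)
  Spf_u <- exp(-(.trans_H(spec, 1, u, treated) +
                 .trans_H(spec, 2, u, treated)))
  h12_u <- .trans_h(spec, 1, u, treated)
  H23 <- function(t) .trans_H(spec, 3, t, treated)
  du <- step / fine
  reset <- spec$clocks[3] == "reset"
  H23_u <- if (!reset) H23(u) else NULL
  prog <- vapply(report, function(t) {
    if (t == 0) return(0)
    iu <- u <= t + 1e-12
    uu <- u[iu]
    surv23 <- if (reset) exp(-H23(t - uu))
              else exp(-(H23(t) - H23_u[iu]))
    f <- Spf_u[iu] * h12_u[iu] * surv23
    ## h12 may be infinite at u = 0 for sub-unit shapes; drop the endpoint
    f[!is.finite(f)] <- 0
    sum((f[-1] + f[-length(f)]) / 2) * du
  }, numeric(1))
  Spf <- exp(-(.trans_H(spec, 1, report, treated) +
               .trans_H(spec, 2, report, treated)))
  occupancy_trace(report, pf = Spf, prog = pmin(prog, 1 - Spf),
                  dead = pmax(1 - Spf - pmin(prog, 1 - Spf), 0),
                  tol = 1e-6)
}
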