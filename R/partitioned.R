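#' Bundled CLL-8 model parameters
#'
#' Loaders for the parameter fixtures shipped with the package: the published
#' regression output of the CLL-8 rituximab trial for the partitioned
#' survival approach, the semi-Markov multi-state model, and the
#' manufacturer's Markov cohort assumptions.
#'
#' @param path Optional path to an alternative YAML file in the same schema.
#' @return A named list of parameters (see the fixture files under
#'   \code{system.file("extdata", package = "idmcea")} for the schema).
#' @export
cll8_partitioned_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cll8_partitioned.yaml",
                        package = "idmcea", mustWork = TRUE)
  yaml::read_yaml(path)
}

## build a hazard_model from a fixture block
.model_from_block <- function(block) {
  hazard_model(block$family, unlist(block$params),
               coefficients = if (!is.null(block$coefficients))
                 unlist(block$coefficients) else NULL,
               standard_errors = if (!is.null(block$standard_errors))
                 unlist(block$standard_errors) else NULL)
}

## membership trace from OS and PFS curves; flooring logged via attribute
.membership <- function(time, os, pfs) {
  prog <- os - pfs
  nfloor <- sum(prog < -1e-12)
  prog <- pmax(prog, 0)
  tr <- occupancy_trace(time, pf = pmin(pfs, os), prog = prog,
                        dead = 1 - pmin(pfs, os) - prog)
  attr(tr, "floored_points") <- nfloor
  tr
}

#' Partitioned survival model from published coefficients
#'
#' Builds per-arm progression-free survival (PFS) and overall survival (OS)
#' curves from a parameter set in the schema of
#' \code{\link{cll8_partitioned_params}} and derives state membership:
#' progression-free = PFS, progression = OS - PFS (floored at zero), dead =
#' 1 - OS.  OS is an exponential over the observed period stitched at the
#' boundary to a Weibull tail evaluated at absolute study time; the treated
#' arm's extrapolation raises the control tail to the observed-period hazard
#' ratio.  PFS is a single Weibull with a proportional-hazards treatment
#' effect over the whole horizon.
#'
#' @param params Parameter list (default: the bundled CLL-8 fixture).
#' @param horizon Time horizon in years (default from \code{params}).
#' @param step Grid step in years (default 1/12).
#' @return Object of class \code{"partitioned_model"}: list with \code{grid},
#'   \code{curves} (\code{pfs}/\code{os} per arm) and \code{membership}
#'   (an \code{\link{occupancy_trace}} per arm, names \code{RFC}/\code{FC}).
#' @export
partitioned_from_params <- function(params = cll8_partitioned_params(),
                                    horizon = NULL, step = 1 / 12) {
  need <- c("pfs", "os_observed", "os_tail", "boundary")
  if (!all(need %in% names(params)))
    stop("parameter fixture is missing: ",
         paste(setdiff(need, names(params)), collapse = ", "))
  if (is.null(horizon)) horizon <- params$horizon %||% 15
  grid <- seq(0, horizon, by = step)
  pfs_m <- .model_from_block(params$pfs)
  os_m <- .model_from_block(params$os_observed)
  tail_m <- .model_from_block(params$os_tail)
  boundary <- params$boundary
  hr_os <- exp(params$os_observed$coefficients$treat)

  pfs <- list(FC = survival_curve(grid, hsurv(pfs_m, grid, c(treat = 0))),
              RFC = survival_curve(grid, hsurv(pfs_m, grid, c(treat = 1))))
  tail_fc <- function(t) hsurv(tail_m, t)
  os <- list(
    FC = stitch(function(t) hsurv(os_m, t, c(treat = 0)), tail_fc,
                junction = boundary, grid = grid),
    RFC = stitch(function(t) hsurv(os_m, t, c(treat = 1)),
                 function(t) tail_fc(t)^hr_os,
                 junction = boundary, grid = grid))
  membership <- list(RFC = .membership(grid, os$RFC$surv, pfs$RFC$surv),
                     FC = .membership(grid, os$FC$surv, pfs$FC$surv))
  structure(list(grid = grid, curves = list(pfs = pfs, os = os),
                 membership = membership, params = params,
                 models = list(pfs = pfs_m, os_observed = os_m,
                               os_tail = tail_m)),
            class = "partitioned_model")
}

#' @export
print.partitioned_model <- function(x, ...) {
  cat("Partitioned survival model,",
      sprintf("horizon %g years, %d grid points\n",
              max(x$grid), length(x$grid)))
  for (arm in names(x$membership)) {
    tr <- x$membership[[arm]]
    cat(sprintf("  %s: S_os(4y) = %.3f, S_pfs(4y) = %.3f\n", arm,
                x$curves$os[[arm]]$surv[which.min(abs(x$grid - 4))],
                x$curves$pfs[[arm]]$surv[which.min(abs(x$grid - 4))]))
  }
  invisible(x)
}

#' Partitioned survival model fitted to individual patient data
#'
#' Derives the PFS (progression or death) and OS (death) outcomes from wide
#' IPD, fits the six standard families to each with a proportional-hazards /
#' AFT treatment effect, and reports an AIC table.  The working model per
#' outcome is the AIC-best family (\code{selection = "aic"}) or a named
#' choice (\code{selection = "fixed"}).  If the selected OS model does not
#' reach zero by the horizon in either arm (survival above \code{zero_tol}),
#' the Kaplan-Meier tail procedure is applied instead: an observed-period
#' exponential fit, a Weibull tail selected by \code{\link{select_tail_start}}
#' on the control arm, and a hazard-ratio-mapped treated-arm extrapolation.
#'
#' @param ipd Wide IPD (see \code{\link{ipd_to_records}}), with \code{arm}
#'   coded 1 = RFC-like treated arm, 0 = FC-like control.
#' @param families Candidate families.
#' @param selection \code{"aic"} or \code{"fixed"}.
#' @param fixed Named list \code{list(pfs = , os = )} of families when
#'   \code{selection = "fixed"}.
#' @param horizon,step Grid settings (years).
#' @param zero_tol Zero-by-horizon threshold (default 0.005).
#' @return A \code{"partitioned_model"} with an extra \code{diagnostics}
#'   element (AIC tables, selected families, tail path details).
#' @export
partitioned_from_ipd <- function(ipd,
                                 families = c("exponential", "weibull",
                                              "gompertz", "loglogistic",
                                              "lognormal", "gengamma"),
                                 selection = c("aic", "fixed"), fixed = NULL,
                                 horizon = 15, step = 1 / 12,
                                 zero_tol = 0.005) {
  selection <- match.arg(selection)
  prog <- !is.na(ipd$t_progression)
  died <- !is.na(ipd$t_death)
  pfs_rec <- data.frame(tstart = 0,
                        tstop = ifelse(prog, ipd$t_progression,
                                       ifelse(died, ipd$t_death,
                                              ipd$t_censor)),
                        status = as.integer(prog | died), treat = ipd$arm)
  os_rec <- data.frame(tstart = 0,
                       tstop = ifelse(died, ipd$t_death, ipd$t_censor),
                       status = as.integer(died), treat = ipd$arm)

  fit_menu <- function(rec) {
    fits <- lapply(families, function(f)
      tryCatch(fit_parametric(rec, f, "treat"), error = function(e) NULL))
    names(fits) <- families
    ok <- !vapply(fits, is.null, logical(1))
    aics <- vapply(fits[ok], aic, numeric(1))
    list(fits = fits[ok], aic = aics)
  }
  pfs_menu <- fit_menu(pfs_rec)
  os_menu <- fit_menu(os_rec)
  pick <- function(menu, which_fixed) {
    if (selection == "fixed") {
      if (is.null(fixed[[which_fixed]]))
        stop("selection = 'fixed' needs fixed$", which_fixed)
      menu$fits[[fixed[[which_fixed]]]]
    } else menu$fits[[names(which.min(menu$aic))]]
  }
  pfs_fit <- pick(pfs_menu, "pfs")
  os_fit <- pick(os_menu, "os")

  grid <- seq(0, horizon, by = step)
  pfs <- list(FC = survival_curve(grid, hsurv(pfs_fit, grid, c(treat = 0))),
              RFC = survival_curve(grid, hsurv(pfs_fit, grid, c(treat = 1))))

  os_zero_ok <- max(hsurv(os_fit, horizon, c(treat = 0)),
                    hsurv(os_fit, horizon, c(treat = 1))) <= zero_tol
  tail_info <- NULL
  if (os_zero_ok) {
    os <- list(FC = survival_curve(grid, hsurv(os_fit, grid, c(treat = 0))),
               RFC = survival_curve(grid, hsurv(os_fit, grid, c(treat = 1))))
  } else {
    ## tail path: observed-period exponential + control-arm KM tail
    exp_fit <- fit_parametric(os_rec, "exponential", "treat")
    hr_obs <- exp(exp_fit$coefficients[["treat"]])
    fc <- os_rec[os_rec$treat == 0, ]
    km_fc <- km_fit(fc$tstop, fc$status)
    sel <- select_tail_start(km_fc, "weibull", horizon = horizon,
                             zero_tol = zero_tol)
    if (is.na(sel$tail_start))
      stop("no tail start yields an extrapolation reaching zero by ",
           horizon, " years")
    junction <- sel$tail_start
    tail_fc <- function(t) tail_surv(sel$fit, t)
    os <- list(
      FC = stitch(function(t) hsurv(exp_fit, t, c(treat = 0)), tail_fc,
                  junction = junction, grid = grid),
      RFC = stitch(function(t) hsurv(exp_fit, t, c(treat = 1)),
                   function(t) tail_fc(t)^hr_obs,
                   junction = junction, grid = grid))
    tail_info <- list(tail_start = junction, hr_observed = hr_obs,
                      tail_coef = sel$fit$coef)
  }
  membership <- list(RFC = .membership(grid, os$RFC$surv, pfs$RFC$surv),
                     FC = .membership(grid, os$FC$surv, pfs$FC$surv))
  structure(list(grid = grid, curves = list(pfs = pfs, os = os),
                 membership = membership,
                 models = list(pfs = pfs_fit, os = os_fit),
                 diagnostics = list(aic_pfs = pfs_menu$aic,
                                    aic_os = os_menu$aic,
                                    selected = c(pfs = pfs_fit$family,
                                                 os = os_fit$family),
                                    os_whole_curve_ok = os_zero_ok,
                                    tail = tail_info)),
            class = "partitioned_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
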