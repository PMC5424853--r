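#' Run the three-approach Life-Year/QALY comparison
#'
#' Drives the partitioned survival, Markov cohort and semi-Markov multi-state
#' pipelines from published coefficients (\code{mode = "coefficients"}) or
#' from individual patient data (\code{mode = "ipd"}), applies the economic
#' settings to each, and assembles a side-by-side comparison table.
#'
#' @param mode \code{"coefficients"} (bundled or supplied parameter
#'   fixtures) or \code{"ipd"} (fit everything from data).
#' @param approaches Subset of \code{c("partitioned", "markov",
#'   "multistate")}.
#' @param config An \code{\link{econ_config}}.
#' @param seed Integer seed; required when the multi-state approach (path
#'   simulation) or any other stochastic step is requested.
#' @param ipd Wide IPD, required for \code{mode = "ipd"}.
#' @param n_paths Paths for the multi-state simulation (default 5000).
#' @param multistate_engine \code{"simulate"} (path simulation, the
#'   published mechanism) or \code{"numeric"} (deterministic convolution).
#' @param params Optional list overriding the bundled fixtures: elements
#'   \code{partitioned}, \code{markov}, \code{multistate_spec}.
#' @param life_table Optional life table for the Markov cohort arm.
#' @param out_dir Optional directory; when given, the comparison table and
#'   per-approach occupancy traces are written as CSV.
#' @return Object of class \code{"idmcea_comparison"}: list with
#'   \code{summaries} (per approach \code{\link{econ_summary}}),
#'   \code{table} (long data frame: approach, arm, quantity, value),
#'   \code{membership} (per approach, per arm traces), and a
#'   \code{diagnostics} block (e.g. cross-approach incremental differences).
#' @export
run_comparison <- function(mode = c("coefficients", "ipd"),
                           approaches = c("partitioned", "markov",
                                          "multistate"),
                           config = econ_config(), seed = NULL, ipd = NULL,
                           n_paths = 5000,
                           multistate_engine = c("simulate", "numeric"),
                           params = list(), life_table = NULL,
                           out_dir = NULL) {
  mode <- match.arg(mode)
  multistate_engine <- match.arg(multistate_engine)
  approaches <- match.arg(approaches, several.ok = TRUE)
  if ("multistate" %in% approaches && multistate_engine == "simulate" &&
      is.null(seed))
    stop("'seed' is required for the multi-state path simulation")
  if (mode == "ipd" && is.null(ipd)) stop("mode = 'ipd' needs 'ipd'")

  membership <- list()
  if ("partitioned" %in% approaches) {
    pm <- if (mode == "coefficients")
      partitioned_from_params(params$partitioned %||%
                                cll8_partitioned_params(),
                              horizon = config$horizon, step = config$step)
    else partitioned_from_ipd(ipd, horizon = config$horizon,
                              step = config$step)
    membership$partitioned <- pm$membership
  }
  if ("markov" %in% approaches) {
    if (mode == "ipd")
      stop("the Markov cohort arm runs from assigned probabilities; ",
           "use mode = 'coefficients'")
    rules <- transition_rules(params$markov %||% cll8_markov_params(),
                              life_table = life_table)
    membership$markov <- list(
      RFC = run_cohort(rules, "RFC", horizon = config$horizon,
                       cycle_length = config$step),
      FC = run_cohort(rules, "FC", horizon = config$horizon,
                      cycle_length = config$step))
  }
  if ("multistate" %in% approaches) {
    spec <- if (mode == "coefficients")
      params$multistate_spec %||% cll8_multistate_spec()
    else fit_multistate(ipd)
    membership$multistate <- if (multistate_engine == "simulate") list(
      RFC = simulate_paths(spec, treated = TRUE, n_paths = n_paths,
                           seed = seed + 1L, horizon = config$horizon,
                           step = config$step),
      FC = simulate_paths(spec, treated = FALSE, n_paths = n_paths,
                          seed = seed, horizon = config$horizon,
                          step = config$step))
    else list(
      RFC = occupancy_numeric(spec, treated = TRUE,
                              horizon = config$horizon, step = config$step),
      FC = occupancy_numeric(spec, treated = FALSE,
                             horizon = config$horizon, step = config$step))
  }

  summaries <- lapply(membership, econ_summary, config = config)
  table <- do.call(rbind, lapply(names(summaries), function(ap) {
    s <- summaries[[ap]]
    long <- rbind(
      cbind(arm = s$by_arm$arm, s$by_arm[-1]),
      cbind(arm = "Incremental", s$incremental))
    out <- utils::stack(long[-1])
    data.frame(approach = ap, arm = rep(long$arm, ncol(long) - 1),
               quantity = out$ind, value = out$values)
  }))

  diagnostics <- NULL
  if (all(c("partitioned", "markov") %in% names(summaries))) {
    diagnostics <- list(
      partitioned_vs_markov_incr_ly =
        summaries$partitioned$incremental$ly_total -
        (summaries$markov$incremental$ly_pf +
         summaries$markov$incremental$ly_prog))
  }

  out <- structure(list(summaries = summaries, table = table,
                        membership = membership,
                        diagnostics = diagnostics, config = config),
                   class = "idmcea_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    for (ap in names(membership))
      write_trace_csv(membership[[ap]],
                      file.path(out_dir, paste0("trace_", ap, ".csv")))
  }
  out
}

#' @export
print.idmcea_comparison <- function(x, ...) {
  cat("Life-Year/QALY comparison across approaches\n")
  wide <- stats::reshape(
    x$table[x$table$quantity %in% c("ly_total", "qaly_total"), ],
    idvar = c("approach", "arm"), timevar = "quantity",
    direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide$ly_total <- round(wide$ly_total, 3)
  wide$qaly_total <- round(wide$qaly_total, 3)
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Fit the semi-Markov multi-state model to individual patient data
#'
#' Converts wide IPD to transition records (clock reset on progression to
#' death), fits the requested family to each transition by maximum
#' likelihood with a treatment effect, and assembles a
#' \code{\link{multistate_spec}} whose per-transition hazard ratios are the
#' fitted \eqn{\exp(\hat\beta)}.
#'
#' @param ipd Wide IPD.
#' @param family Baseline family for every transition (default
#'   \code{"gompertz"}), or a character vector of three.
#' @return A \code{multistate_spec}; the three fits are attached as
#'   attribute \code{"fits"}.
#' @export
fit_multistate <- function(ipd, family = "gompertz") {
  family <- rep(family, length.out = 3)
  rec <- ipd_to_records(ipd, clock23 = "reset")
  fits <- lapply(1:3, function(i)
    fit_parametric(rec[rec$trans == i, ], family[i], "treat"))
  models <- lapply(fits, function(f)
    hazard_model(f$family, f$params, effect_type = "PH"))
  spec <- multistate_spec(models,
                          hr = vapply(fits, function(f)
                            exp(f$coefficients[["treat"]]), numeric(1)))
  attr(spec, "fits") <- fits
  spec
}

#' Plot state occupancy against observed proportions
#'
#' Draws the modeled probability of being in a state with, optionally, a
#' bootstrap band of observed proportions from IPD.
#'
#' @param traces Named list of \code{\link{occupancy_trace}} objects (one
#'   per approach) for a single arm.
#' @param state State column to draw (default \code{"prog"}).
#' @param band Optional \code{\link{bootstrap_proportion_ci}} result.
#' @param main Plot title.
#' @export
plot_occupancy_comparison <- function(traces, state = "prog", band = NULL,
                                      main = NULL) {
  xr <- range(unlist(lapply(traces, function(tr) tr$time)))
  yr <- c(0, max(unlist(lapply(traces, function(tr) tr[[state]])),
                 if (!is.null(band)) band$high))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "Years",
                 ylab = paste("P(in", state, "state)"), main = main)
  if (!is.null(band))
    graphics::polygon(c(band$grid, rev(band$grid)),
                      c(band$low, rev(band$high)),
                      col = "grey85", border = NA)
  for (i in seq_along(traces))
    graphics::lines(traces[[i]]$time, traces[[i]][[state]], col = i, lty = i)
  graphics::legend("topright", legend = names(traces), col = seq_along(traces),
                   lty = seq_along(traces), bty = "n")
  invisible(NULL)
}

#' Plot a Kaplan-Meier estimate with a model overlay
#'
#' @param km A \code{\link{km_fit}} result.
#' @param curves Optional named list of \code{\link{survival_curve}} objects
#'   to overlay.
#' @param main Title.
#' @export
plot_km_overlay <- function(km, curves = NULL, main = NULL) {
  graphics::plot(stats::stepfun(km$time, c(1, km$surv)), do.points = FALSE,
                 xlab = "Years", ylab = "Survival", main = main,
                 ylim = c(0, 1))
  if (!is.null(curves))
    for (i in seq_along(curves))
      graphics::lines(curves[[i]]$time, curves[[i]]$surv, col = i + 1)
  if (!is.null(curves))
    graphics::legend("topright", legend = c("Kaplan-Meier", names(curves)),
                     col = c(1, seq_along(curves) + 1), lty = 1, bty = "n")
  invisible(NULL)
}
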