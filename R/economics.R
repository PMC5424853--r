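#' Economic evaluation settings
#'
#' @param discount_rate Annual discount rate (default 0.035).
#' @param u_pf,u_prog State utilities for progression-free and progression
#'   (defaults 0.8 and 0.6).
#' @param horizon Time horizon in years (default 15).
#' @param step Integration grid step in years (default 1/12).
#' @param costs Optional named numeric vector of per-arm total costs (same
#'   names as the occupancy traces), or \code{NULL}.
#' @return List of class \code{"econ_config"}.
#' @export
econ_config <- function(discount_rate = 0.035, u_pf = 0.8, u_prog = 0.6,
                        horizon = 15, step = 1 / 12, costs = NULL) {
  stopifnot(discount_rate >= 0, u_pf >= 0, u_pf <= 1, u_prog >= 0,
            u_prog <= 1, horizon > 0, step > 0)
  structure(list(discount_rate = discount_rate, u_pf = u_pf,
                 u_prog = u_prog, horizon = horizon, step = step,
                 costs = costs),
            class = "econ_config")
}

#' Discounted area under a curve by the trapezoidal rule
#'
#' Applies the discount factor \eqn{(1+r)^{-t}} pointwise at each grid time
#' and integrates by the composite trapezoidal rule.  The grid must be
#' uniform.
#'
#' @param time Uniform, increasing time grid (years).
#' @param values Curve values at the grid times (occupancy or survival).
#' @param rate Annual discount rate.
#' @return Discounted area, in years.
#' @export
discounted_area <- function(time, values, rate = 0.035) {
  stopifnot(length(time) == length(values), length(time) >= 2)
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("'time' must be a uniform grid")
  v <- values * (1 + rate)^(-time)
  sum((v[-1] + v[-length(v)]) / 2 * dt)
}

#' Split a discounted area at an observed/extrapolated boundary
#'
#' The two parts add exactly to the whole-horizon area.  An off-grid
#' boundary is snapped to the nearest grid point with a warning.
#'
#' @param time,values,rate As in \code{\link{discounted_area}}.
#' @param boundary Split time in years.
#' @return List with \code{observed}, \code{extrapolated}, \code{boundary}
#'   (after snapping).
#' @export
period_split <- function(time, values, boundary, rate = 0.035) {
  i <- which.min(abs(time - boundary))
  if (abs(time[i] - boundary) > 1e-9) {
    warning("boundary ", boundary, " snapped to grid point ", time[i])
    boundary <- time[i]
  }
  whole <- discounted_area(time, values, rate)
  obs <- if (i == 1) 0 else discounted_area(time[1:i], values[1:i], rate)
  list(observed = obs, extrapolated = whole - obs, boundary = boundary)
}

#' Discounted Life-Year / QALY summary with incrementals
#'
#' Integrates per-state occupancy for each arm into discounted Life Years and
#' QALYs, and forms incremental differences (first arm minus second) and,
#' when costs are supplied, incremental cost-effectiveness ratios.
#'
#' @param membership Named list of two \code{\link{occupancy_trace}} objects;
#'   the first name is treated as the intervention arm.
#' @param config An \code{\link{econ_config}}.
#' @return Object of class \code{"econ_summary"}: list with \code{by_arm}
#'   (data frame of LY/QALY components per arm), \code{incremental}, and
#'   \code{icer} (\code{NA} when costs are absent or the effect difference is
#'   zero).
#' @export
econ_summary <- function(membership, config = econ_config()) {
  stopifnot(length(membership) == 2, !is.null(names(membership)))
  r <- config$discount_rate
  rows <- lapply(names(membership), function(arm) {
    tr <- as.data.frame(membership[[arm]])
    ly_pf <- discounted_area(tr$time, tr$pf, r)
    ly_prog <- discounted_area(tr$time, tr$prog, r)
    data.frame(arm = arm, ly_pf = ly_pf, ly_prog = ly_prog,
               ly_total = ly_pf + ly_prog,
               qaly_pf = config$u_pf * ly_pf,
               qaly_prog = config$u_prog * ly_prog,
               qaly_total = config$u_pf * ly_pf + config$u_prog * ly_prog,
               cost = if (!is.null(config$costs))
                 config$costs[[arm]] else NA_real_)
  })
  by_arm <- do.call(rbind, rows)
  inc <- by_arm[1, -1] - by_arm[2, -1]
  icer <- list(per_ly = NA_real_, per_qaly = NA_real_)
  if (!is.null(config$costs)) {
    if (abs(inc$ly_total) > 0) icer$per_ly <- inc$cost / inc$ly_total
    if (abs(inc$qaly_total) > 0) icer$per_qaly <- inc$cost / inc$qaly_total
  }
  structure(list(by_arm = by_arm, incremental = inc, icer = icer,
                 config = config),
            class = "econ_summary")
}

#' @export
print.econ_summary <- function(x, ...) {
  cat("Discounted Life Years / QALYs",
      sprintf("(r = %.1f%%, horizon %g y)\n",
              100 * x$config$discount_rate, x$config$horizon))
  df <- x$by_arm
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 3)
  print(df, row.names = FALSE)
  cat("Incremental:", sprintf("LY %.3f, QALY %.3f\n",
                              x$incremental$ly_total,
                              x$incremental$qaly_total))
  if (!is.na(x$icer$per_qaly))
    cat(sprintf("ICER: %.0f per LY, %.0f per QALY\n",
                x$icer$per_ly, x$icer$per_qaly))
  invisible(x)
}
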