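#' State occupancy trace
#'
#' Per-state occupancy probabilities of the illness-death model on a time
#' grid, optionally with Monte-Carlo standard errors when produced by path
#' simulation.
#'
#' @param time Time grid (years).
#' @param pf,prog,dead Occupancy probabilities of the progression-free,
#'   progression and death states.
#' @param mc_se Optional list/data frame of Monte-Carlo standard errors with
#'   elements \code{pf}, \code{prog}, \code{dead}.
#' @param tol Tolerance for the sum-to-one check (default \code{1e-9} for
#'   deterministic traces; simulated traces are checked against
#'   \code{3 * mc_se} instead).
#' @return Object of class \code{"occupancy_trace"} (a data frame).
#' @export
occupancy_trace <- function(time, pf, prog, dead, mc_se = NULL, tol = 1e-9) {
  n <- length(time)
  stopifnot(length(pf) == n, length(prog) == n, length(dead) == n)
  tot <- pf + prog + dead
  if (is.null(mc_se)) {
    if (any(abs(tot - 1) > tol))
      stop("state occupancies do not sum to 1 (max deviation ",
           signif(max(abs(tot - 1)), 3), ")")
  }
  out <- data.frame(time = time, pf = pf, prog = prog, dead = dead)
  if (!is.null(mc_se)) {
    out$se_pf <- mc_se$pf; out$se_prog <- mc_se$prog; out$se_dead <- mc_se$dead
  }
  class(out) <- c("occupancy_trace", "data.frame")
  out
}

#' @export
print.occupancy_trace <- function(x, ...) {
  cat(sprintf("Occupancy trace: %d points on [%g, %g]%s\n", nrow(x),
              min(x$time), max(x$time),
              if ("se_pf" %in% names(x)) " (simulated, with MC SEs)" else ""))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Plot a state occupancy trace
#'
#' @param x An \code{\link{occupancy_trace}}.
#' @param states Which states to draw.
#' @param ... Passed to \code{matplot}.
#' @export
plot.occupancy_trace <- function(x, states = c("pf", "prog", "dead"), ...) {
  graphics::matplot(x$time, as.matrix(as.data.frame(x)[states]), type = "l",
                    lty = 1, xlab = "Years", ylab = "State occupancy", ...)
  graphics::legend("topright", legend = states, lty = 1,
                   col = seq_along(states), bty = "n")
  invisible(x)
}

#' Write occupancy traces to CSV
#'
#' @param traces Named list of \code{\link{occupancy_trace}} objects (names
#'   are treatment arms).
#' @param path Output CSV path; columns \code{time, arm, pf, prog, dead}.
#' @export
write_trace_csv <- function(traces, path) {
  rows <- lapply(names(traces), function(arm) {
    tr <- as.data.frame(traces[[arm]])
    data.frame(time = tr$time, arm = arm, pf = tr$pf, prog = tr$prog,
               dead = tr$dead)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}
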