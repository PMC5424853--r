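#' Markov cohort transition rules
#'
#' Assembles the manufacturer-style transition-probability assumptions of the
#' monthly-cycle three-state cohort model: a constant progression-to-death
#' probability (derived from the reciprocal of a Kaplan-Meier mean
#' post-progression survival), a per-arm observed probability of death while
#' progression-free (replaced by an age-specific background mortality
#' probability whenever that is larger), and a stay-in-progression-free
#' probability taken from a Weibull progression-free survival regression.
#'
#' @param params Fixture list in the schema of
#'   \code{\link{cll8_markov_params}} (the default loads the bundled CLL-8
#'   assumptions).
#' @param life_table Optional data frame with columns \code{age} and
#'   \code{annual_q} (annual mortality probability).
#' @param cohort_start_age Cohort age in years at model start (default 61;
#'   only used when a life table is supplied).
#' @return List of class \code{"transition_rules"}.
#' @export
transition_rules <- function(params = cll8_markov_params(),
                             life_table = NULL, cohort_start_age = 61) {
  p_prog_death <- rate_to_probability(
    1 / params$post_progression_km_mean_months)
  pfs_model <- .model_from_block(params$pfs)
  if (!is.null(life_table) &&
      !all(c("age", "annual_q") %in% names(life_table)))
    stop("life_table needs columns 'age' and 'annual_q'")
  structure(list(p_prog_death = p_prog_death,
                 p_pf_death = unlist(params$p_pf_death_monthly),
                 pfs_model = pfs_model,
                 life_table = life_table,
                 cohort_start_age = cohort_start_age,
                 horizon = params$horizon %||% 15),
            class = "transition_rules")
}

#' @rdname transition_rules
#' @param path Optional alternative YAML fixture path.
#' @export
cll8_markov_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cll8_markov_cohort.yaml",
                        package = "idmcea", mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Read a life table CSV
#'
#' @param path CSV with columns \code{age} and \code{annual_q}.
#' @return Data frame.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  if (!all(c("age", "annual_q") %in% names(lt)))
    stop("life table needs columns 'age' and 'annual_q'")
  lt
}

#' Per-cycle probability of staying progression-free
#'
#' Conditional survival of the progression-free survival model over one
#' cycle: \eqn{S((k+1)/12\,|\,x)/S(k/12\,|\,x)}.
#'
#' @param pfs_model A \code{\link{hazard_model}} for progression-free
#'   survival.
#' @param k Cycle index (0-based); vectorized.
#' @param covariates Covariates for the model (e.g. \code{c(treat = 1)}).
#' @param cycle_length Cycle length in years (default 1/12).
#' @return Probability of remaining progression-free over cycle \code{k}.
#' @export
stay_probability <- function(pfs_model, k, covariates = NULL,
                             cycle_length = 1 / 12) {
  s0 <- hsurv(pfs_model, k * cycle_length, covariates)
  s1 <- hsurv(pfs_model, (k + 1) * cycle_length, covariates)
  ifelse(s0 <= 0, 0, s1 / s0)
}

#' Monthly probability of death while progression-free
#'
#' The observed per-arm monthly probability, or the age-specific background
#' mortality probability, whichever is larger.  Background annual
#' probabilities are converted to monthly by the compound rule
#' \eqn{1 - (1-q)^{1/12}}.  Ages beyond the life table carry the last row
#' forward with a warning.
#'
#' @param rules A \code{\link{transition_rules}}.
#' @param k Cycle index (0-based).
#' @param arm Arm name matching \code{rules$p_pf_death}.
#' @param cycle_length Cycle length in years (default 1/12).
#' @return Monthly probability of death while progression-free.
#' @export
pf_death_probability <- function(rules, k, arm, cycle_length = 1 / 12) {
  observed <- rules$p_pf_death[[arm]]
  lt <- rules$life_table
  if (is.null(lt)) return(rep(observed, length(k)))
  age <- rules$cohort_start_age + k * cycle_length
  if (any(age > max(lt$age)))
    warning("cohort age beyond life table; last row carried forward")
  q <- stats::approx(lt$age, lt$annual_q, xout = pmin(age, max(lt$age)),
                     method = "constant", rule = 2)$y
  pmax(observed, 1 - (1 - q)^(1 / 12))
}

#' Run the discrete-time three-state cohort model
#'
#' Propagates a cohort from progression-free through monthly cycles:
#' \code{pf} decays by the stay probability; the flow out of \code{pf} that
#' is not death goes to progression; progression empties into death at the
#' constant progression-to-death probability.  Occupancy is conserved
#' exactly.
#'
#' The progression state can be clocked two ways: \code{"reset"} tracks the
#' cohort in progression by time since entry (tunnel accounting), applying
#' the progression-to-death probability by state-age; \code{"forward"}
#' applies it by cycle index.  With the constant probability used here the
#' two are identical (the state is memoryless).
#'
#' @param rules A \code{\link{transition_rules}}.
#' @param arm Arm name.
#' @param covariates Covariates for the stay model (default
#'   \code{c(treat = 1)} for arm \code{"RFC"}, \code{c(treat = 0)}
#'   otherwise).
#' @param horizon Years (default from rules).
#' @param cycle_length Cycle length in years (default 1/12).
#' @param prog_clock \code{"reset"} or \code{"forward"}.
#' @return An \code{\link{occupancy_trace}} at cycle boundaries.
#' @export
run_cohort <- function(rules, arm, covariates = NULL, horizon = NULL,
                       cycle_length = 1 / 12,
                       prog_clock = c("reset", "forward")) {
  prog_clock <- match.arg(prog_clock)
  if (is.null(horizon)) horizon <- rules$horizon
  if (is.null(covariates))
    covariates <- c(treat = as.numeric(identical(arm, "RFC")))
  n_cycle <- round(horizon / cycle_length)
  k <- 0:(n_cycle - 1)
  stay <- stay_probability(rules$pfs_model, k, covariates, cycle_length)
  p_pf_death <- pf_death_probability(rules, k, arm, cycle_length)
  if (cycle_length != 1 / 12) {
    ## fixture probabilities are monthly; re-express for the chosen cycle
    p_pf_death <- rate_to_probability(
      probability_to_rate(p_pf_death, 1 / 12), cycle_length)
  }
  p_prog_death <- if (cycle_length == 1 / 12) rules$p_prog_death
    else rate_to_probability(probability_to_rate(rules$p_prog_death, 1 / 12),
                             cycle_length)
  if (any(1 - stay - p_pf_death < -1e-12))
    stop("negative progression inflow: stay + death probability exceeds 1")

  pf <- numeric(n_cycle + 1); prog <- numeric(n_cycle + 1)
  dead <- numeric(n_cycle + 1)
  pf[1] <- 1
  ## tunnel accounting for the progression state (time-since-entry ages)
  prog_by_age <- numeric(0)
  for (i in seq_len(n_cycle)) {
    inflow <- pf[i] * pmax(1 - stay[i] - p_pf_death[i], 0)
    death_from_pf <- pf[i] * p_pf_death[i]
    if (prog_clock == "reset") {
      deaths_prog <- sum(prog_by_age) * p_prog_death
      prog_by_age <- c(inflow, prog_by_age * (1 - p_prog_death))
      prog[i + 1] <- sum(prog_by_age)
    } else {
      deaths_prog <- prog[i] * p_prog_death
      prog[i + 1] <- prog[i] * (1 - p_prog_death) + inflow
    }
    pf[i + 1] <- pf[i] * stay[i]
    dead[i + 1] <- dead[i] + death_from_pf + deaths_prog
    ## absorb numerical residue into death so occupancy is conserved
    dead[i + 1] <- 1 - pf[i + 1] - prog[i + 1]
  }
  occupancy_trace(time = (0:n_cycle) * cycle_length, pf = pf, prog = prog,
                  dead = dead)
}
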