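#' Eligibility-trace coefficients
#'
#' Computes the trace coefficient `lambda = 1 - (1 - dt/kappa)/(1 - dt/tau)`
#' and the discount-linked coefficient `gamma = 1 - dt/tau`. The per-step
#' trace decay factor is their product `lambda * gamma`.
#'
#' @param kappa trace time constant (default 9.6).
#' @param tau TD time constant (default 10); must exceed `dt`.
#' @param dt timestep width (default 1).
#' @return named list with `lambda`, `gamma` and `decay = lambda * gamma`.
#' @export
#' @examples
#' trace_coefficients()         # gamma = 0.9, lambda ~ 0.00463
trace_coefficients <- function(kappa = 9.6, tau = 10, dt = 1) {
  if (dt <= 0 || dt >= tau)
    stop("dt must lie in (0, tau): discount factor undefined", call. = FALSE)
  if (dt >= kappa) stop("dt must be smaller than kappa", call. = FALSE)
  gamma <- 1 - dt / tau
  lambda <- 1 - (1 - dt / kappa) / (1 - dt / tau)
  list(lambda = lambda, gamma = gamma, decay = lambda * gamma)
}

#' Index of the active complete-serial-compound unit
#'
#' The CSC is a tapped delay line: unit `n` of the presented stimulus fires at
#' `t = cue_onset + (n - 1)`; all other units (and the whole vector of the
#' non-presented stimulus) are 0.
#'
#' @param t timestep in `[1, T]`.
#' @param cue_onset cue onset step.
#' @param n_units delay-line length.
#' @return the index of the unit that is 1 at `t`, or `NA_integer_` if no unit
#'   is active (before cue onset or past the line's end).
#' @export
csc_active_unit <- function(t, cue_onset = 25L, n_units = 100L) {
  n <- t - cue_onset + 1L
  ifelse(n >= 1L & n <= n_units, as.integer(n), NA_integer_)
}

#' Binary CSC activation map at one timestep
#'
#' @param t timestep.
#' @param stimulus presented stimulus id (1 or 2).
#' @param cfg model configuration ([atp_config()]).
#' @param n_stimuli number of stimulus vectors.
#' @return an `n_units x n_stimuli` 0/1 matrix with at most a single 1.
#' @export
csc_activation <- function(t, stimulus, cfg = atp_config(), n_stimuli = 2L) {
  if (!is.numeric(stimulus) || length(stimulus) != 1L ||
      !(stimulus %in% seq_len(n_stimuli)))
    stop("protocol error: invalid stimulus id ", deparse(substitute(stimulus)),
         " (must be in 1..", n_stimuli, ")", call. = FALSE)
  phi <- matrix(0, cfg$critic$n_units, n_stimuli)
  n <- csc_active_unit(t, cfg$trial$cue_onset, cfg$critic$n_units)
  if (!is.na(n)) phi[n, stimulus] <- 1
  phi
}

#' Fresh eligibility traces
#'
#' @param cfg model configuration.
#' @param n_stimuli number of stimulus vectors.
#' @return an `n_units x n_stimuli` matrix of zeros.
#' @export
new_traces <- function(cfg = atp_config(), n_stimuli = 2L) {
  matrix(0, cfg$critic$n_units, n_stimuli)
}

#' One-step eligibility trace update
#'
#' In the default `unit_onset` mode every trace decays geometrically by
#' `lambda * gamma` each step and the unit firing at `t` is set to 1.
#' In `reward_onset` mode (the literal reading in which traces are pinned at 1
#' until reward onset) all units that have fired so far hold 1 while
#' `t < reinforcer_onset` and decay only afterwards.
#'
#' @param traces current trace matrix (`n_units x n_stimuli`).
#' @param t timestep.
#' @param stimulus presented stimulus id.
#' @param cfg model configuration.
#' @return updated trace matrix.
#' @export
update_traces <- function(traces, t, stimulus, cfg = atp_config()) {
  co <- trace_coefficients(cfg$critic$kappa, cfg$critic$tau, cfg$trial$dt)
  n <- csc_active_unit(t, cfg$trial$cue_onset, cfg$critic$n_units)
  if (cfg$critic$trace_mode == "unit_onset") {
    traces <- traces * co$decay
    if (!is.na(n)) traces[n, stimulus] <- 1
  } else {
    if (t < cfg$trial$reinforcer_onset) {
      if (!is.na(n)) traces[seq_len(n), stimulus] <- 1
    } else {
      traces <- traces * co$decay
    }
  }
  traces
}
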