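#' Fresh model state
#'
#' Allocates the learnable state of one simulated subject: the magnitude and
#' omission critic weight matrices (all zero — a naive subject), the 4 x 2
#' association weight matrix (pre-synaptic S1, S2, Om, Rew; post-synaptic R1,
#' R2) and the expectancy meta-parameters. Node activations and eligibility
#' traces are per-trial quantities and live in the trial loop, not here.
#'
#' @param cfg model configuration.
#' @param n_stimuli number of discriminative stimuli.
#' @return list of class `atp_state` with elements `theta_m`, `theta_o`,
#'   `omega`, `meta`.
#' @export
atp_state <- function(cfg = atp_config(), n_stimuli = 2L) {
  structure(list(
    theta_m = matrix(0, cfg$critic$n_units, n_stimuli),
    theta_o = matrix(0, cfg$critic$n_units, n_stimuli),
    omega = matrix(0, 4L, 2L,
                   dimnames = list(c("S1", "S2", "Om", "Rew"), c("R1", "R2"))),
    meta = meta_params(cfg)
  ), class = "atp_state")
}

#' @export
print.atp_state <- function(x, ...) {
  cat("<atp_state>\n")
  cat(sprintf("  max theta_m: %.4f  max theta_o: %.4f\n",
              max(x$theta_m), max(x$theta_o)))
  cat("  association weights:\n")
  print(round(x$omega, 4))
  cat(sprintf("  meta: slope(vm)=%.2f th(vm)=%.3f slope(vo)=%.2f th(vo)=%.3f\n",
              x$meta[["beta_vm"]], x$meta[["th_vm"]],
              x$meta[["beta_vo"]], x$meta[["th_vo"]]))
  invisible(x)
}

#' Run one trial (reference R engine)
#'
#' Executes the `T`-step trial loop: CSC/critic update, expectancy
#' computation, node dynamics, response selection at `target_offset - 1`,
#' probabilistic reinforcement at `reinforcer_onset`, prediction-error-gated
#' learning each step, and meta-parameter plasticity at the reinforcer
#' evaluation step. Consumes exactly two uniform draws (decision, reinforcer)
#' regardless of branch, so lesioned and ablated variants see identical
#' random streams.
#'
#' This is the readable single-trial reference; [run_experiment()] uses a
#' compiled translation of the same loop by default and the two are held
#' equal draw-for-draw in the test suite.
#'
#' @param state model state ([atp_state()]), modified copy returned.
#' @param stimulus presented stimulus (1 or 2).
#' @param p reinforcement probability for a correct response on this trial.
#' @param correct_resp the schedule's correct response for this stimulus.
#' @param extinction if `TRUE` the reinforcer is withheld regardless of `p`.
#' @param guess_p1 undriven-guess probability of response 1.
#' @param cfg model configuration.
#' @param detail if `TRUE`, also return a per-step data frame of node and
#'   critic trajectories.
#' @return list with `state`, `record` (one-row data frame) and, if requested,
#'   `detail`.
#' @export
run_trial_r <- function(state, stimulus, p, correct_resp, extinction = FALSE,
                        guess_p1 = 0.5, cfg = atp_config(), detail = FALSE) {
  tr <- cfg$trial; cr <- cfg$critic; ac <- cfg$actor
  if (!(stimulus %in% c(1L, 2L)))
    stop("protocol error: invalid stimulus id ", stimulus, call. = FALSE)
  co <- trace_coefficients(cr$kappa, cr$tau, tr$dt)
  cscale <- if (isTRUE(cr$euler_scale)) tr$dt / cr$tau else 1
  n_units <- cr$n_units
  traces <- matrix(0, n_units, ncol(state$theta_m))
  # node order: S1, S2, R1, R2
  u <- c(ac$s_h, ac$s_h, ac$r_h, ac$r_h)
  vm_prev <- 0; vo_prev <- 0
  chosen <- 0L; driven <- FALSE; rewarded <- FALSE
  rew_dec <- om_dec <- vm_dec <- vo_dec <- NA_real_
  exec_end <- tr$reinforcer_offset + ac$exec_extra
  gate_neg_do <- identical(ac$gate_sr, "neg_delta_o")
  gate_om_neg <- identical(ac$gate_om, "neg_delta_o")
  rw_rule <- identical(ac$er_rule, "rw_outcome")
  om_always <- identical(cr$om_coupling, "always")
  inhibit <- !isTRUE(cfg$ablate$mutual_inhibition)
  steps <- if (detail) vector("list", tr$T) else NULL

  for (t in seq_len(tr$T)) {
    n <- t - tr$cue_onset + 1L
    has_unit <- n >= 1L && n <= n_units
    vm <- if (has_unit) clamp01(state$theta_m[n, stimulus]) else 0
    vo <- if (has_unit) clamp01(state$theta_o[n, stimulus]) else 0
    lam_prev <- if (rewarded &&
                    (t - cr$reward_lag) >= tr$reinforcer_onset &&
                    (t - cr$reward_lag) < tr$reinforcer_offset) 1 else 0
    d_m <- delta_magnitude(lam_prev, vm, vm_prev, cr$tau, tr$dt)
    outcome_now <- t >= tr$reinforcer_onset + cr$reward_lag &&
      t < tr$reinforcer_offset + cr$reward_lag
    d_o <- delta_omission(if (om_always || outcome_now) d_m else 0,
                          vo, vo_prev, cr$tau, tr$dt)
    # credit the traces as they stood at the end of step t-1
    state$theta_m[, stimulus] <- state$theta_m[, stimulus] +
      cr$beta_m * cscale * max(0, d_m) * traces[, stimulus]
    th_o <- state$theta_o[, stimulus] +
      cr$beta_o * cscale * d_o * traces[, stimulus]
    if (is.finite(cr$theta_o_min)) th_o <- pmax(th_o, cr$theta_o_min)
    state$theta_o[, stimulus] <- th_o
    if (cr$trace_mode == "unit_onset") {
      traces <- traces * co$decay
      if (has_unit) traces[n, stimulus] <- 1
    } else {
      if (t < tr$reinforcer_onset) {
        if (has_unit) traces[seq_len(n), stimulus] <- 1
      } else traces <- traces * co$decay
    }
    # expectancies from previous-step values (Eqs. use V(t-1))
    pm <- min(vm_prev * ac$value_gain, 1)
    po <- min(vo_prev * ac$value_gain, 1)
    lm <- sigmoid(pm, state$meta[["beta_vm"]], state$meta[["th_vm"]])
    lo <- sigmoid(po, state$meta[["beta_vo"]], state$meta[["th_vo"]])
    if (isTRUE(ac$rew_outer_sigmoid)) {
      rew <- sigmoid(lm - if (inhibit) lo else 0, cfg$meta$beta_om, cfg$meta$th_om)
    } else {
      rew <- max(lm - if (inhibit) lo else 0, 0)
    }
    om <- sigmoid(lo - if (inhibit) rew else 0, cfg$meta$beta_om, cfg$meta$th_om)
    # inputs from pre-update activities (synchronous update)
    a_s1 <- sigmoid(u[1], ac$s_beta); a_s2 <- sigmoid(u[2], ac$s_beta)
    in_cue <- t >= tr$cue_onset & t < tr$cue_offset
    in_tgt <- t >= tr$target_onset & t < tr$target_offset
    I_s1 <- as.numeric((stimulus == 1L && (in_cue || in_tgt)) ||
                         (isTRUE(ac$both_target_inputs) && in_tgt))
    I_s2 <- as.numeric((stimulus == 2L && (in_cue || in_tgt)) ||
                         (isTRUE(ac$both_target_inputs) && in_tgt))
    I_r <- state$omega["S1", ] * a_s1 + state$omega["S2", ] * a_s2 +
      state$omega["Om", ] * om + state$omega["Rew", ] * rew
    if (chosen > 0L && t >= tr$target_offset && t < exec_end) {
      I_r[chosen] <- I_r[chosen] + ac$exec_input
      I_r[3L - chosen] <- I_r[3L - chosen] - ac$exec_input
    }
    u[1] <- step_node(u[1], I_s1, ac$s_tau, ac$s_h, ac$s_C, ac$s_beta, tr$dt)
    u[2] <- step_node(u[2], I_s2, ac$s_tau, ac$s_h, ac$s_C, ac$s_beta, tr$dt)
    u[3] <- step_node(u[3], I_r[1], ac$r_tau, ac$r_h, ac$r_C, ac$r_beta, tr$dt)
    u[4] <- step_node(u[4], I_r[2], ac$r_tau, ac$r_h, ac$r_C, ac$r_beta, tr$dt)
    o_r1 <- sigmoid(u[3], ac$r_beta); o_r2 <- sigmoid(u[4], ac$r_beta)
    if (t == tr$target_offset - 1L) {
      u_draw <- stats::runif(1)   # always consumed: draw-count invariance
      sel <- select_response(o_r1, o_r2, guess_p1, ac$decision_threshold,
                             u = u_draw)
      chosen <- sel$response; driven <- sel$driven
      rew_dec <- rew; om_dec <- om; vm_dec <- vm; vo_dec <- vo
    }
    if (t == tr$reinforcer_onset) {
      u2 <- stats::runif(1)
      rewarded <- !extinction && chosen == correct_resp && u2 < p
    }
    # association learning from post-update activities
    as1 <- sigmoid(u[1], ac$s_beta); as2 <- sigmoid(u[2], ac$s_beta)
    outcome_step <- outcome_now
    if (rw_rule) {
      # delta rule toward the outcome indicator at the outcome-news step
      if (outcome_step) {
        lam_tr <- as.numeric(rewarded)
        pre <- c(as1, as2, om, rew)
        beta_k <- c(ac$beta_sr, ac$beta_sr, ac$beta_er, ac$beta_er)
        rows <- c(!cfg$lesion$s_r, !cfg$lesion$s_r,
                  !cfg$lesion$e_r, !cfg$lesion$e_r)
        for (k in which(rows)) {
          state$omega[k, ] <- state$omega[k, ] +
            beta_k[k] * pre[k] * c(o_r1, o_r2) * (lam_tr - state$omega[k, ])
        }
      }
    } else {
      gate <- if (gate_neg_do) -d_o else d_m
      learn_now <- identical(ac$assoc_window, "all") || outcome_step
      if (learn_now && !isTRUE(cfg$lesion$s_r)) {
        state$omega["S1", ] <- state$omega["S1", ] +
          ac$beta_sr * gate * as1 * c(o_r1, o_r2)
        state$omega["S2", ] <- state$omega["S2", ] +
          ac$beta_sr * gate * as2 * c(o_r1, o_r2)
      }
      if (learn_now && !isTRUE(cfg$lesion$e_r)) {
        state$omega["Om", ] <- state$omega["Om", ] +
          ac$beta_er * (if (gate_om_neg) -d_o else d_o) * om * c(o_r1, o_r2)
        state$omega["Rew", ] <- state$omega["Rew", ] +
          ac$beta_er * gate * rew * c(o_r1, o_r2)
      }
      if (learn_now && is.finite(ac$omega_min))
        state$omega[state$omega < ac$omega_min] <- ac$omega_min
    }
    if (t == tr$reinforcer_offset) {
      state$meta <- update_meta_params(state$meta, d_o, I_r = 1, cfg)
    }
    if (detail) {
      steps[[t]] <- data.frame(t = t, unit = if (has_unit) n else NA_integer_,
                               vm = vm, vo = vo, delta_m = d_m, delta_o = d_o,
                               rew = rew, om = om,
                               u_s1 = u[1], u_s2 = u[2], u_r1 = u[3], u_r2 = u[4],
                               reward = lam_prev)
    }
    vm_prev <- vm; vo_prev <- vo
  }
  record <- data.frame(
    stimulus = stimulus, response = chosen, driven = driven,
    correct = chosen == correct_resp, rewarded = rewarded,
    rew_dec = rew_dec, om_dec = om_dec, vm_dec = vm_dec, vo_dec = vo_dec
  )
  out <- list(state = state, record = record)
  if (detail) out$detail <- do.call(rbind, steps)
  out
}

#' Run a phase of trials with the reference R engine
#'
#' @param state model state.
#' @param stimuli integer vector of presented stimuli (the trial order).
#' @param p_by_stim reinforcement probability per stimulus.
#' @param correct_by_stim correct response per stimulus.
#' @param extinction whether this phase withholds all reinforcers.
#' @param guess_p1 undriven-guess probability of response 1.
#' @param cfg model configuration.
#' @return list with updated `state` and a `records` data frame
#'   (one row per trial).
#' @export
run_phase_r <- function(state, stimuli, p_by_stim, correct_by_stim,
                        extinction = FALSE, guess_p1 = 0.5,
                        cfg = atp_config()) {
  recs <- vector("list", length(stimuli))
  for (i in seq_along(stimuli)) {
    s <- stimuli[i]
    out <- run_trial_r(state, s, p_by_stim[s], correct_by_stim[s],
                       extinction, guess_p1, cfg)
    state <- out$state
    recs[[i]] <- out$record
  }
  list(state = state, records = do.call(rbind, recs))
}
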