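#' Sigmoidal transfer function
#'
#' `Lambda(u, beta, th) = 1 / (1 + exp(-beta * (u - th)))`, the nonlinear
#' transformation applied to all actor node activations and to the expectancy
#' inputs.
#'
#' @param u activation (numeric vector).
#' @param beta gain (slope); must be positive.
#' @param th threshold.
#' @return values in `(0, 1)`.
#' @export
#' @examples
#' sigmoid(1, beta = 2)   # ~0.8808
sigmoid <- function(u, beta = 1, th = 0) {
  if (any(beta <= 0)) stop("sigmoid gain beta must be positive", call. = FALSE)
  1 / (1 + exp(-beta * (u - th)))
}

#' One backward-Euler step of an Amari node
#'
#' `u(t) = u(t-dt) + (dt/tau) * (-u(t-dt) + h + C * Lambda(u(t-dt), beta) + I)`.
#'
#' @param u current activation.
#' @param I summed input at this step.
#' @param tau node time constant (> 0).
#' @param h resting level.
#' @param C self-excitation gain.
#' @param beta transfer-function gain used in the self-excitation term.
#' @param dt timestep width.
#' @return updated activation.
#' @export
step_node <- function(u, I, tau = 10, h = -1, C = 1.2, beta = 4, dt = 1) {
  if (tau <= 0) stop("node time constant tau must be positive", call. = FALSE)
  u + (dt / tau) * (-u + h + C * sigmoid(u, beta) + I)
}

#' Fresh meta-parameters for the expectancy sigmoids
#'
#' The four meta-parameters are the slopes and thresholds of the sigmoids
#' reading the (normalised) magnitude and omission values into the Rew and Om
#' expectancy nodes. They are plastic: the omission prediction error sharpens
#' the congruent classifier (slope up, threshold toward zero) at each
#' reinforcer evaluation.
#'
#' @param cfg model configuration.
#' @return named numeric vector `c(beta_vm, th_vm, beta_vo, th_vo)`.
#' @export
meta_params <- function(cfg = atp_config()) {
  c(beta_vm = cfg$meta$init_slope, th_vm = cfg$meta$init_th,
    beta_vo = cfg$meta$init_slope, th_vo = cfg$meta$init_th)
}

#' Reward and omission expectancies from the critic values
#'
#' `Rew = rectify( Lambda(Vm', x_beta_vm, x_th_vm) - Lambda(Vo', x_beta_vo, x_th_vo) )`
#' and `Om = Lambda( Lambda(Vo', ...) - Rew, beta_om, th_om )`, where `Vm'`,
#' `Vo'` are the previous-step values normalised by `actor$value_gain` (and
#' capped at 1) so the sigmoids operate on the probability scale. Mutual
#' inhibition (each expectancy suppressing the other) can be ablated, in which
#' case both subtraction terms are dropped.
#'
#' @param vm_prev,vo_prev critic values at the previous timestep.
#' @param meta meta-parameter vector as produced by `meta_params()`.
#' @param cfg model configuration.
#' @return list with `rew` and `om`, both in `[0, 1]`.
#' @export
compute_expectancies <- function(vm_prev, vo_prev, meta, cfg = atp_config()) {
  pm <- min(vm_prev * cfg$actor$value_gain, 1)
  po <- min(vo_prev * cfg$actor$value_gain, 1)
  lm <- sigmoid(pm, meta[["beta_vm"]], meta[["th_vm"]])
  lo <- sigmoid(po, meta[["beta_vo"]], meta[["th_vo"]])
  inhibit <- !isTRUE(cfg$ablate$mutual_inhibition)
  if (isTRUE(cfg$actor$rew_outer_sigmoid)) {
    rew <- sigmoid(lm - if (inhibit) lo else 0, cfg$meta$beta_om, cfg$meta$th_om)
  } else {
    rew <- max(lm - if (inhibit) lo else 0, 0)
  }
  om <- sigmoid(lo - if (inhibit) rew else 0, cfg$meta$beta_om, cfg$meta$th_om)
  list(rew = rew, om = om)
}

#' Prediction-error-driven meta-parameter plasticity
#'
#' Each meta-parameter moves by `psi_s * delta_o / (C_j * I_r)` and is clamped
#' to its bounds. The signs implement congruent sharpening: a positive omission
#' prediction error raises the omission slope and lowers the omission
#' threshold; a positive reward prediction error (`-delta_o`) raises the
#' reward slope and lowers the reward threshold.
#'
#' @param meta meta-parameter vector.
#' @param delta_o omission prediction error at the evaluation step.
#' @param I_r reinforcer-window drive gating the update; if 0 the update is
#'   skipped (division guard).
#' @param cfg model configuration.
#' @return updated meta-parameter vector.
#' @export
update_meta_params <- function(meta, delta_o, I_r = 1, cfg = atp_config()) {
  if (I_r == 0) return(meta)
  if (isTRUE(cfg$meta$rectified)) {
    # congruent sharpening only: the omission classifier moves on positive
    # omission PE, the reward classifier on positive reward PE (-delta_o)
    step_om <- max(delta_o, 0) / (cfg$meta$C_j * I_r)
    step_rew <- max(-delta_o, 0) / (cfg$meta$C_j * I_r)
    meta <- meta + c(beta_vm = step_rew, th_vm = -step_rew,
                     beta_vo = step_om, th_vo = -step_om)[names(meta)]
  } else {
    step <- delta_o / (cfg$meta$C_j * I_r)
    psi <- c(beta_vm = -1, th_vm = +1, beta_vo = +1, th_vo = -1)
    meta <- meta + psi[names(meta)] * step
  }
  meta[["beta_vm"]] <- min(max(meta[["beta_vm"]], cfg$meta$slope_min), cfg$meta$slope_max)
  meta[["beta_vo"]] <- min(max(meta[["beta_vo"]], cfg$meta$slope_min), cfg$meta$slope_max)
  meta[["th_vm"]] <- min(max(meta[["th_vm"]], cfg$meta$th_min), cfg$meta$th_max)
  meta[["th_vo"]] <- min(max(meta[["th_vo"]], cfg$meta$th_min), cfg$meta$th_max)
  meta
}

#' Prediction-error-gated Hebbian update of association weights
#'
#' `Omega_kl += beta_e * delta_e * a_k * a_l` for pre-synaptic activity `a_k`
#' and post-synaptic activity `a_l` — the linear TD-gated Hebbian form. The
#' simulation engine uses this form when `actor$er_rule = "pe_hebbian"` (with
#' the gating error per connection class set by `actor$gate_sr` /
#' `actor$gate_om`); the default engine rule is the outcome delta rule
#' described in `atp_config()` and the methods vignette, under which weights
#' converge to the reward probability given pre/post co-activity.
#'
#' @param omega weight matrix (pre-nodes x post-nodes).
#' @param pre,post activity vectors (sigmoided node outputs / expectancies).
#' @param delta gating prediction error (scalar, signed).
#' @param beta learning rate in `[0, 1)`.
#' @return updated weight matrix.
#' @export
update_association_weights <- function(omega, pre, post, delta, beta) {
  if (beta < 0 || beta >= 1)
    stop("beta must be a learning rate in [0, 1)", call. = FALSE)
  omega + beta * delta * outer(pre, post)
}

#' Response selection at decision time
#'
#' If the larger of the two sigmoided response-node outputs reaches the
#' decision threshold, the response with the larger output is selected (exact
#' ties broken by the supplied uniform draw). Otherwise an undriven guess is
#' made: uniform over the two responses for a two-lever protocol, response 1
#' with probability 0.25 for the single-rule (four-permutation) protocol.
#'
#' @param out1,out2 sigmoided response-node outputs at the decision step.
#' @param guess_p1 probability that an undriven guess selects response 1.
#' @param threshold decision threshold on the outputs.
#' @param u a uniform(0, 1) draw consumed for the guess or tie-break.
#' @return list with `response` (1 or 2) and `driven` (logical).
#' @export
select_response <- function(out1, out2, guess_p1 = 0.5, threshold = 0.5,
                            u = stats::runif(1)) {
  if (max(out1, out2) >= threshold) {
    if (out1 == out2) {
      list(response = if (u < 0.5) 1L else 2L, driven = TRUE)
    } else {
      list(response = if (out1 > out2) 1L else 2L, driven = TRUE)
    }
  } else {
    list(response = if (u < guess_p1) 1L else 2L, driven = FALSE)
  }
}
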