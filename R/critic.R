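#' Clamp a value to the unit interval
#'
#' The critic's piecewise output nonlinearity: 0 below 0, identity on
#' `[0, 1)`, 1 at or above 1.
#'
#' @param x numeric vector.
#' @return `pmin(pmax(x, 0), 1)`.
#' @export
clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Critic value for one dimension
#'
#' `V_e(t) = clamp( sum_n sum_s theta_e[n, s] * phi[n, s] )`.
#'
#' @param theta weight matrix (`n_units x n_stimuli`) for dimension `e`.
#' @param phi binary activation map of the same dimensions.
#' @return scalar value in `[0, 1]`.
#' @export
compute_value <- function(theta, phi) {
  if (!all(dim(theta) == dim(phi)))
    stop("theta and phi must have identical dimensions", call. = FALSE)
  clamp01(sum(theta * phi))
}

#' Magnitude prediction error
#'
#' `delta_m(t) = lambda(t - dt) + (tau/dt) * ((1 - dt/tau) * Vm(t) - Vm(t - dt))`.
#' The raw signed value is returned; clipping to non-negative values happens
#' only inside the magnitude weight update.
#'
#' @param reward_prev reward signal at the previous step, in `[0, 1]`.
#' @param vm_now,vm_prev magnitude value at the current/previous step.
#' @param tau TD time constant.
#' @param dt timestep width.
#' @return signed prediction error.
#' @export
delta_magnitude <- function(reward_prev, vm_now, vm_prev, tau = 10, dt = 1) {
  reward_prev + (tau / dt) * ((1 - dt / tau) * vm_now - vm_prev)
}

#' Omission prediction error
#'
#' `delta_o(t) = -delta_m(t) + (tau/dt) * ((1 - dt/tau) * Vo(t) - Vo(t - dt))`.
#'
#' @param delta_m_raw raw signed magnitude prediction error.
#' @param vo_now,vo_prev omission value at the current/previous step.
#' @param tau TD time constant.
#' @param dt timestep width.
#' @return signed prediction error.
#' @export
delta_omission <- function(delta_m_raw, vo_now, vo_prev, tau = 10, dt = 1) {
  -delta_m_raw + (tau / dt) * ((1 - dt / tau) * vo_now - vo_prev)
}

#' Prediction-error-gated critic weight update
#'
#' `theta(t) = theta(t - dt) + beta * delta * trace` applied elementwise over
#' units and stimuli. For the magnitude dimension the prediction error is first
#' clipped to `max(0, delta)` so magnitude weights never decrease; the omission
#' dimension uses the signed error.
#'
#' @param theta weight matrix.
#' @param delta scalar prediction error for this dimension.
#' @param traces eligibility trace matrix.
#' @param beta learning rate in `[0, 1)`.
#' @param dimension `"m"` (magnitude, non-negative gating) or `"o"` (omission).
#' @return updated weight matrix.
#' @export
update_critic_weights <- function(theta, delta, traces, beta,
                                  dimension = c("m", "o")) {
  dimension <- match.arg(dimension)
  if (beta < 0 || beta >= 1)
    stop("beta must be a learning rate in [0, 1)", call. = FALSE)
  if (dimension == "m") delta <- max(0, delta)
  theta + beta * delta * traces
}
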