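#' Default model configuration
#'
#' Returns the full set of model constants as a nested list. Every numeric
#' constant used by the simulator is reachable from here; user code overrides
#' entries by passing a modified copy to [run_experiment()] or by supplying a
#' YAML file to [load_config()].
#'
#' @section Trial timing:
#' A trial is `T = 100` unit timesteps. The discriminative cue is on during
#' `[cue_onset, cue_offset)`, the response targets during
#' `[target_onset, target_offset)`, and the reinforcer occupies the single step
#' `[reinforcer_onset, reinforcer_offset)`. The cue-offset-to-reinforcer
#' interval is 22 steps. A response is read out at `target_offset - 1`.
#'
#' @section Critic:
#' `kappa` and `tau` parameterise the eligibility-trace coefficients
#' `lambda = 1 - (1 - dt/kappa)/(1 - dt/tau)` and `gamma = 1 - dt/tau`;
#' `beta_m`/`beta_o` are the magnitude/omission critic learning rates.
#' The converged value one step before a unit reinforcer is `dt/tau` (0.1),
#' discounted backward by `gamma` per step, so expectancy readouts are
#' normalised by `value_gain = tau/dt` onto the probability scale.
#'
#' @param ... named overrides applied on top of the defaults; nested values are
#'   addressed as e.g. `critic = list(beta_o = 0.2)` (partial lists are merged).
#' @return a nested list of class `atp_config`.
#' @export
#' @examples
#' cfg <- atp_config(critic = list(beta_o = 0.2))
#' cfg$critic$beta_o
atp_config <- function(...) {
  cfg <- list(
    trial = list(
      T = 100L,
      cue_onset = 25L,
      cue_offset = 50L,
      target_onset = 57L,
      target_offset = 72L,
      reinforcer_onset = 72L,
      reinforcer_offset = 73L,
      dt = 1
    ),
    critic = list(
      n_units = 100L,
      kappa = 9.6,
      tau = 10,
      beta_m = 0.06,
      beta_o = 0.42,
      reward_lag = 1L,           # delta uses lambda(t - reward_lag * dt)
      trace_mode = "unit_onset", # or "reward_onset" (traces pinned until reward)
      euler_scale = TRUE,        # scale weight updates by dt/tau (continuous-time
                                 # reading; the deltas carry a tau/dt factor)
      om_coupling = "outcome",   # -delta_m enters delta_o at the reinforcer
                                 # evaluation step only ("always" = literal)
      theta_o_min = 0            # omission weight floor (-Inf = unconstrained)
    ),
    actor = list(
      # S1/S2 cue nodes: standard dynamic-field settings
      s_tau = 10, s_h = -1, s_C = 1.2, s_beta = 4,
      # R1/R2 response nodes: shallow resting level, sharp transfer, no
      # self-excitation, so association weights of order 0.1 discriminate
      r_tau = 10, r_h = -0.1, r_C = 0, r_beta = 10,
      decision_threshold = 0.5,
      exec_input = 5,        # execution drive to the chosen response node
      exec_extra = 2L,       # execution window extends this far past reinforcer offset
      value_gain = 10,       # tau/dt: normalises V onto the probability scale
      beta_sr = 0.30,
      beta_er = 0.06,
      er_rule = "rw_outcome",   # association rule: delta-rule toward the outcome
                                # indicator ("pe_hebbian" = linear TD-PE gate)
      gate_sr = "neg_delta_o",  # pe_hebbian only: PE gating S-R and Rew-R
      gate_om = "neg_delta_o",  # pe_hebbian only: gating of Om-R ("delta_o")
      assoc_window = "reinforcer",  # when association learning applies ("all")
      omega_min = 0,         # synaptic floor (excitatory weights; -Inf = unconstrained)
      both_target_inputs = FALSE,
      rew_outer_sigmoid = FALSE
    ),
    meta = list(
      beta_om = 10, th_om = 0.45,
      C_j = 3,
      rectified = TRUE,   # sharpen each classifier on its congruent PE only
      slope_min = 4, slope_max = 20,
      th_min = 0.2, th_max = 0.7,
      init_slope = 4, init_th = 0.5
    ),
    lesion = list(s_r = FALSE, e_r = FALSE),
    ablate = list(mutual_inhibition = FALSE)
  )
  modifyList(cfg, .merge_overrides(list(...)), keep.null = FALSE) |>
    structure(class = "atp_config") |>
    validate_config()
}

.merge_overrides <- function(ov) {
  if (length(ov) && (is.null(names(ov)) || any(names(ov) == "")))
    stop("configuration overrides must be named", call. = FALSE)
  ov
}

#' Validate a model configuration
#'
#' Checks ranges and orderings (learning rates in \[0, 1), timing landmarks in
#' increasing order, `dt < tau`) and fails naming the offending key.
#'
#' @param cfg a configuration list as produced by [atp_config()].
#' @return `cfg`, invisibly unchanged, or an error.
#' @export
validate_config <- function(cfg) {
  tr <- cfg$trial
  need <- c("trial", "critic", "actor", "meta", "lesion", "ablate")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("configuration is missing section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  with(tr, {
    if (!(cue_onset < cue_offset && cue_offset < target_onset &&
          target_onset <= target_offset && target_offset <= reinforcer_onset &&
          reinforcer_onset < reinforcer_offset && reinforcer_offset <= T))
      stop("trial: timing landmarks must satisfy cue_onset < cue_offset < ",
           "target_onset <= target_offset <= reinforcer_onset < ",
           "reinforcer_offset <= T", call. = FALSE)
  })
  if (tr$dt <= 0 || tr$dt >= cfg$critic$tau)
    stop("trial$dt must lie in (0, critic$tau): discount undefined otherwise",
         call. = FALSE)
  if (tr$dt >= cfg$critic$kappa)
    stop("trial$dt must be smaller than critic$kappa", call. = FALSE)
  for (k in c("beta_m", "beta_o")) {
    b <- cfg$critic[[k]]
    if (!is.numeric(b) || b < 0 || b >= 1)
      stop("critic$", k, " must be a learning rate in [0, 1)", call. = FALSE)
  }
  for (k in c("beta_sr", "beta_er")) {
    b <- cfg$actor[[k]]
    if (!is.numeric(b) || b < 0 || b >= 1)
      stop("actor$", k, " must be a learning rate in [0, 1)", call. = FALSE)
  }
  if (!cfg$actor$er_rule %in% c("rw_outcome", "pe_hebbian"))
    stop("actor$er_rule must be \"rw_outcome\" or \"pe_hebbian\"", call. = FALSE)
  if (!cfg$actor$gate_sr %in% c("neg_delta_o", "delta_m"))
    stop("actor$gate_sr must be \"neg_delta_o\" or \"delta_m\"", call. = FALSE)
  if (!cfg$actor$gate_om %in% c("neg_delta_o", "delta_o"))
    stop("actor$gate_om must be \"neg_delta_o\" or \"delta_o\"", call. = FALSE)
  if (!cfg$actor$assoc_window %in% c("reinforcer", "all"))
    stop("actor$assoc_window must be \"reinforcer\" or \"all\"", call. = FALSE)
  if (!cfg$critic$trace_mode %in% c("unit_onset", "reward_onset"))
    stop("critic$trace_mode must be \"unit_onset\" or \"reward_onset\"",
         call. = FALSE)
  if (!cfg$critic$om_coupling %in% c("outcome", "always"))
    stop("critic$om_coupling must be \"outcome\" or \"always\"", call. = FALSE)
  if (cfg$meta$slope_min > cfg$meta$slope_max ||
      cfg$meta$th_min > cfg$meta$th_max)
    stop("meta: parameter bounds must satisfy min <= max", call. = FALSE)
  invisible(cfg)
}

#' Load and validate a configuration (and optional protocol) from YAML
#'
#' Reads a YAML file whose top level may contain any [atp_config()] section
#' plus an optional `protocol:` block (fields of [protocol_spec()], or
#' `name: <bundled protocol>` to start from a bundled definition). Unknown
#' top-level keys trigger a warning; invalid values an error naming the key.
#'
#' @param path path to a YAML file.
#' @return list with elements `config` (class `atp_config`) and `protocol`
#'   (a `protocol_spec` or `NULL`).
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "example_config.yaml",
#'                                package = "atpsim"))
#' cfg$protocol$n_runs
load_config <- function(path) {
  if (!file.exists(path)) stop("no such configuration file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("trial", "critic", "actor", "meta", "lesion", "ablate", "protocol")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("ignoring unknown configuration key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  proto <- NULL
  if (!is.null(raw$protocol)) {
    pr <- raw$protocol
    if (!is.null(pr$name)) {
      proto <- bundled_protocol(pr$name)
      pr$name <- NULL
      for (k in names(pr)) proto[[k]] <- pr[[k]]
      proto <- validate_protocol(proto)
    } else {
      proto <- do.call(protocol_spec, pr)
    }
  }
  cfg <- do.call(atp_config, raw[setdiff(names(raw), c("protocol", unknown))])
  list(config = cfg, protocol = proto)
}

#' @export
print.atp_config <- function(x, ...) {
  cat("<atp_config>\n")
  cat(sprintf("  trial: T=%d cue [%d,%d) target [%d,%d) reinforcer [%d,%d)\n",
              x$trial$T, x$trial$cue_onset, x$trial$cue_offset,
              x$trial$target_onset, x$trial$target_offset,
              x$trial$reinforcer_onset, x$trial$reinforcer_offset))
  cat(sprintf("  critic: beta_m=%.3g beta_o=%.3g kappa=%.3g tau=%.3g (%s traces)\n",
              x$critic$beta_m, x$critic$beta_o, x$critic$kappa, x$critic$tau,
              x$critic$trace_mode))
  cat(sprintf("  actor : beta_sr=%.3g beta_er=%.3g gate_sr=%s threshold=%.2f\n",
              x$actor$beta_sr, x$actor$beta_er, x$actor$gate_sr,
              x$actor$decision_threshold))
  les <- c(if (x$lesion$s_r) "S-R", if (x$lesion$e_r) "E-R")
  cat(sprintf("  lesion: %s%s\n",
              if (length(les)) paste(les, collapse = "+") else "none",
              if (x$ablate$mutual_inhibition) " (mutual inhibition ablated)" else ""))
  invisible(x)
}
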