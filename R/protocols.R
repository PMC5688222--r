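#' Declarative experiment protocol
#'
#' A protocol names the discrimination task (which response is correct for
#' each stimulus, with what reinforcement probability), the phase structure
#' (acquisition, extinction, optionally re-acquisition), block sizes for
#' balancing/reporting, and the batch settings (number of runs, seed base).
#'
#' @param name protocol identifier.
#' @param kind `"two_lever"` (undriven guesses uniform over the two responses)
#'   or `"single_rule"` (undriven guesses select response 1 with probability
#'   0.25, the four-permutation button abstraction).
#' @param p reinforcement probability per stimulus (length 2, each in `[0, 1]`).
#' @param correct correct response per stimulus (length 2, values 1 or 2).
#' @param component component label per stimulus (e.g. `c("CRF", "PRF")`).
#' @param phases list of phases, each a list with `name`, `trials`,
#'   `block_size` and `extinction` (logical). `trials` must be a multiple of
#'   `block_size`, and `block_size` even (for exact within-block balance).
#' @param n_runs number of seeded runs in a batch.
#' @param seed_base seed of run 1; run `r` uses `seed_base + r - 1`.
#' @param max_same_run maximum run length of identical consecutive stimuli.
#' @return list of class `protocol_spec`.
#' @export
protocol_spec <- function(name, kind = c("two_lever", "single_rule"),
                          p, correct, component = c("A", "B"),
                          phases = list(), n_runs = 50L, seed_base = 1L,
                          max_same_run = 3L) {
  kind <- match.arg(kind)
  spec <- structure(list(
    name = name, kind = kind,
    p = as.numeric(p), correct = as.integer(correct),
    component = as.character(component),
    guess_p1 = if (kind == "two_lever") 0.5 else 0.25,
    phases = phases, n_runs = as.integer(n_runs),
    seed_base = as.integer(seed_base), max_same_run = as.integer(max_same_run)
  ), class = "protocol_spec")
  validate_protocol(spec)
}

#' Validate a protocol
#' @param spec a `protocol_spec`.
#' @return `spec` invisibly, or an error naming the offending field.
#' @export
validate_protocol <- function(spec) {
  if (length(spec$p) != 2L || any(spec$p < 0 | spec$p > 1))
    stop("protocol$p must be two reinforcement probabilities in [0, 1]",
         call. = FALSE)
  if (length(spec$correct) != 2L || !all(spec$correct %in% c(1L, 2L)))
    stop("protocol$correct must give a response in {1, 2} per stimulus",
         call. = FALSE)
  if (!length(spec$phases)) stop("protocol needs at least one phase", call. = FALSE)
  for (ph in spec$phases) {
    if (ph$trials <= 0 || ph$trials %% ph$block_size != 0)
      stop("phase \"", ph$name, "\": trials must be a positive multiple of ",
           "block_size", call. = FALSE)
    if (ph$block_size %% 2L != 0L)
      stop("phase \"", ph$name, "\": block_size must be even for exact ",
           "stimulus balance", call. = FALSE)
  }
  if (spec$n_runs < 1L) stop("protocol$n_runs must be positive", call. = FALSE)
  if (spec$max_same_run < 1L)
    stop("protocol$max_same_run must be at least 1", call. = FALSE)
  invisible(spec)
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> %s (%s)\n", x$name, x$kind))
  for (s in 1:2)
    cat(sprintf("  S%d -> R%d at p = %.2f  [%s]\n",
                s, x$correct[s], x$p[s], x$component[s]))
  for (ph in x$phases)
    cat(sprintf("  phase %-14s %3d trials in blocks of %d%s\n", ph$name,
                ph$trials, ph$block_size,
                if (isTRUE(ph$extinction)) " (extinction)" else ""))
  cat(sprintf("  %d runs, seed base %d, max same-stimulus run %d\n",
              x$n_runs, x$seed_base, x$max_same_run))
  invisible(x)
}

.phase <- function(name, trials, block_size, extinction = FALSE) {
  list(name = name, trials = as.integer(trials),
       block_size = as.integer(block_size), extinction = extinction)
}

#' Bundled protocols
#'
#' Ready-made definitions of the simulated experiments:
#' * `ko_expl` — two-lever within-subjects discrimination, S1->R1 continuously
#'   reinforced (p = 1.0), S2->R2 partially (p = 0.5); 240 acquisition trials
#'   reported as 6 blocks of 40, then 40 extinction trials as 4 blocks of 10.
#' * `ko_crf`, `ko_prf` — the between-subjects controls (both components at
#'   p = 1.0, resp. p = 0.5).
#' * `svartdal_multi` — single-rule task, S1 and S2 both map to R1 at high
#'   (0.8) / low (0.4) reward density; 180 acquisition + 40 extinction trials
#'   in blocks of 10.
#' * `svartdal_high`, `svartdal_low` — both components at 0.8, resp. 0.4.
#'
#' @param name one of the protocol names above.
#' @param n_runs,seed_base batch settings (defaults 50 runs, seed base 1).
#' @return a [protocol_spec()].
#' @export
bundled_protocol <- function(name, n_runs = 50L, seed_base = 1L) {
  ko_phases <- list(.phase("acquisition", 240L, 40L),
                    .phase("extinction", 40L, 10L, TRUE))
  sv_phases <- list(.phase("acquisition", 180L, 10L),
                    .phase("extinction", 40L, 10L, TRUE))
  switch(name,
    ko_expl = protocol_spec("ko_expl", "two_lever", p = c(1, 0.5),
                            correct = c(1L, 2L), component = c("CRF", "PRF"),
                            phases = ko_phases, n_runs = n_runs,
                            seed_base = seed_base),
    ko_crf = protocol_spec("ko_crf", "two_lever", p = c(1, 1),
                           correct = c(1L, 2L), component = c("A", "B"),
                           phases = ko_phases, n_runs = n_runs,
                           seed_base = seed_base),
    ko_prf = protocol_spec("ko_prf", "two_lever", p = c(0.5, 0.5),
                           correct = c(1L, 2L), component = c("A", "B"),
                           phases = ko_phases, n_runs = n_runs,
                           seed_base = seed_base),
    svartdal_multi = protocol_spec("svartdal_multi", "single_rule",
                                   p = c(0.8, 0.4), correct = c(1L, 1L),
                                   component = c("high", "low"),
                                   phases = sv_phases, n_runs = n_runs,
                                   seed_base = seed_base),
    svartdal_high = protocol_spec("svartdal_high", "single_rule",
                                  p = c(0.8, 0.8), correct = c(1L, 1L),
                                  component = c("A", "B"),
                                  phases = sv_phases, n_runs = n_runs,
                                  seed_base = seed_base),
    svartdal_low = protocol_spec("svartdal_low", "single_rule",
                                 p = c(0.4, 0.4), correct = c(1L, 1L),
                                 component = c("A", "B"),
                                 phases = sv_phases, n_runs = n_runs,
                                 seed_base = seed_base),
    stop("unknown bundled protocol \"", name, "\"; valid names: ko_expl, ",
         "ko_crf, ko_prf, svartdal_multi, svartdal_high, svartdal_low",
         call. = FALSE)
  )
}

#' Pseudo-random balanced trial sequence
#'
#' Draws a stimulus order for one phase: each block contains both stimuli
#' equally often, and no more than `max_same` identical stimuli occur in
#' succession (the cap is enforced across block boundaries too). Blocks are
#' shuffled by rejection sampling.
#'
#' @param n_trials phase length.
#' @param block_size balancing block size (even).
#' @param max_same maximum same-stimulus run length.
#' @param n_stimuli number of stimuli.
#' @return integer vector of stimulus ids, length `n_trials`.
#' @export
generate_trial_sequence <- function(n_trials, block_size, max_same = 3L,
                                    n_stimuli = 2L) {
  if (n_trials %% block_size != 0L || block_size %% n_stimuli != 0L)
    stop("n_trials must be a multiple of block_size, and block_size a ",
         "multiple of n_stimuli", call. = FALSE)
  if (max_same < 1L) stop("max_same must be at least 1", call. = FALSE)
  base <- rep(seq_len(n_stimuli), each = block_size %/% n_stimuli)
  out <- integer(0)
  for (b in seq_len(n_trials %/% block_size)) {
    for (attempt in seq_len(10000L)) {
      cand <- sample(base)
      # check run lengths from just before the block boundary through the block
      window <- c(out, cand)[seq.int(max(1L, length(out) - max_same + 1L),
                                     length(out) + block_size)]
      if (max(rle(window)$lengths) <= max_same) break
      if (attempt == 10000L)
        stop("could not satisfy the run-length constraint; it is infeasible ",
             "for this block_size/max_same combination", call. = FALSE)
    }
    out <- c(out, cand)
  }
  out
}
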