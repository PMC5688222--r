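#' Run a seeded batch of simulated subjects through a protocol
#'
#' Simulates `runs` independent model instances (run `r` seeded with
#' `seed_base + r - 1`) through every phase of the protocol, and aggregates
#' per-trial records into per-block correct-choice proportions.
#'
#' @param spec a [protocol_spec()] or the name of a [bundled_protocol()].
#' @param cfg model configuration ([atp_config()]).
#' @param runs number of runs; defaults to the protocol's `n_runs`.
#' @param seed_base seed of the first run; defaults to the protocol's.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation); the two are draw-for-draw identical.
#' @param keep_state if `TRUE`, the final [atp_state()] of every run is
#'   returned in `states`.
#' @return list of class `atp_result` with elements:
#'   * `trials`: data frame with `run`, `phase`, `trial` (index within phase),
#'     `block`, `stimulus`, `component`, `response`, `driven`, `correct`,
#'     `rewarded`, and decision-time `rew_dec`, `om_dec`, `vm_dec`, `vo_dec`;
#'   * `blocks`: per-run block proportions from [block_proportions()];
#'   * `spec`, `cfg`, and optionally `states`.
#' @export
#' @examples
#' \donttest{
#' res <- run_experiment("ko_expl", runs = 2, seed_base = 1)
#' head(res$blocks)
#' }
run_experiment <- function(spec, cfg = atp_config(), runs = NULL,
                           seed_base = NULL, engine = c("cpp", "r"),
                           keep_state = FALSE) {
  if (is.character(spec)) spec <- bundled_protocol(spec)
  validate_protocol(spec)
  validate_config(cfg)
  engine <- match.arg(engine)
  runs <- if (is.null(runs)) spec$n_runs else as.integer(runs)
  seed_base <- if (is.null(seed_base)) spec$seed_base else as.integer(seed_base)
  if (runs < 1L) stop("runs must be positive", call. = FALSE)

  trial_list <- vector("list", runs)
  states <- if (keep_state) vector("list", runs) else NULL
  for (r in seq_len(runs)) {
    set.seed(seed_base + r - 1L)
    state <- atp_state(cfg)
    run_recs <- vector("list", length(spec$phases))
    for (pi in seq_along(spec$phases)) {
      ph <- spec$phases[[pi]]
      stimuli <- generate_trial_sequence(ph$trials, ph$block_size,
                                         spec$max_same_run)
      out <- if (engine == "cpp") {
        .run_phase_cpp(state, stimuli, spec$p, spec$correct,
                       isTRUE(ph$extinction), spec$guess_p1, cfg)
      } else {
        run_phase_r(state, stimuli, spec$p, spec$correct,
                    isTRUE(ph$extinction), spec$guess_p1, cfg)
      }
      state <- out$state
      rec <- out$records
      rec$run <- r
      rec$phase <- ph$name
      rec$trial <- seq_len(nrow(rec))
      rec$block <- ((rec$trial - 1L) %/% ph$block_size) + 1L
      rec$component <- spec$component[rec$stimulus]
      run_recs[[pi]] <- rec
    }
    trial_list[[r]] <- do.call(rbind, run_recs)
    if (keep_state) states[[r]] <- state
  }
  trials <- do.call(rbind, trial_list)
  rownames(trials) <- NULL
  front <- c("run", "phase", "trial", "block", "stimulus", "component")
  trials <- trials[, c(front, setdiff(names(trials), front))]
  structure(list(trials = trials, blocks = block_proportions(trials),
                 spec = spec, cfg = cfg, states = states),
            class = "atp_result")
}

#' @export
print.atp_result <- function(x, ...) {
  cat(sprintf("<atp_result> %s: %d runs, %d trials/run\n", x$spec$name,
              max(x$trials$run), nrow(x$trials) / max(x$trials$run)))
  print(block_summary(x$blocks), digits = 3)
  invisible(x)
}

#' Per-run block proportions of correct choice
#'
#' @param trials the `trials` data frame of an [run_experiment()] result.
#' @return data frame with `run`, `phase`, `block`, `stimulus`, `component`,
#'   `n` and `prop_correct`.
#' @export
block_proportions <- function(trials) {
  agg <- stats::aggregate(
    cbind(correct = trials$correct),
    by = list(run = trials$run, phase = trials$phase, block = trials$block,
              stimulus = trials$stimulus, component = trials$component),
    FUN = mean
  )
  n <- stats::aggregate(
    cbind(n = rep(1L, nrow(trials))),
    by = list(run = trials$run, phase = trials$phase, block = trials$block,
              stimulus = trials$stimulus, component = trials$component),
    FUN = sum
  )
  out <- merge(agg, n)
  names(out)[names(out) == "correct"] <- "prop_correct"
  out[order(out$run, out$phase, out$block, out$stimulus),
      c("run", "phase", "block", "stimulus", "component", "n", "prop_correct")]
}

#' Across-run block summary (mean, SEM, 95% CI)
#'
#' @param blocks per-run block proportions from [block_proportions()].
#' @return data frame with one row per phase x block x component carrying the
#'   across-run mean proportion correct, its standard error and normal 95%
#'   confidence limits.
#' @export
block_summary <- function(blocks) {
  splits <- split(blocks, list(blocks$phase, blocks$block, blocks$component),
                  drop = TRUE)
  rows <- lapply(splits, function(d) {
    m <- mean(d$prop_correct)
    sem <- stats::sd(d$prop_correct) / sqrt(nrow(d))
    data.frame(phase = d$phase[1], block = d$block[1],
               stimulus = d$stimulus[1], component = d$component[1],
               n_runs = nrow(d), mean = m, sem = sem,
               ci_lo = m - 1.96 * sem, ci_hi = m + 1.96 * sem)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$phase, out$block, out$stimulus), ]
}

#' Mean proportion correct over a window of blocks
#'
#' Convenience accessor used by the analysis functions: per-run means for one
#' phase, optionally restricted to a set of blocks, by component.
#'
#' @param blocks per-run block proportions.
#' @param phase phase name.
#' @param which_blocks integer vector of block indices (default: all).
#' @return data frame `run` x `component` -> `mean_correct` (wide by
#'   component).
#' @export
phase_means <- function(blocks, phase, which_blocks = NULL) {
  d <- blocks[blocks$phase == phase, ]
  if (!is.null(which_blocks)) d <- d[d$block %in% which_blocks, ]
  if (!nrow(d)) stop("no blocks selected for phase \"", phase, "\"", call. = FALSE)
  agg <- stats::aggregate(cbind(mean_correct = d$prop_correct),
                          by = list(run = d$run, component = d$component),
                          FUN = mean)
  stats::reshape(agg, idvar = "run", timevar = "component", direction = "wide",
                 sep = "_")
}
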