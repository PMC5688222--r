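#' Write experiment outputs and a reproducibility manifest
#'
#' Serialises an `atp_result` to `trials.csv` and `blocks.csv` under `dir`,
#' together with `manifest.json` recording the protocol, the full
#' configuration, the seed list, the package version and per-file checksums —
#' enough, with the codebase, to reproduce every output byte.
#'
#' @param result an `atp_result`.
#' @param dir output directory (created if missing).
#' @param prefix optional file-name prefix.
#' @return invisibly, the manifest list.
#' @export
write_result <- function(result, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trials = file.path(dir, paste0(prefix, "trials.csv")),
             blocks = file.path(dir, paste0(prefix, "blocks.csv")))
  utils::write.csv(result$trials, paths[["trials"]], row.names = FALSE)
  utils::write.csv(result$blocks, paths[["blocks"]], row.names = FALSE)
  runs <- max(result$trials$run)
  manifest <- list(
    protocol = result$spec[setdiff(names(result$spec), "phases")],
    phases = result$spec$phases,
    config = unclass(result$cfg),
    seeds = result$spec$seed_base + seq_len(runs) - 1L,
    package_version = as.character(utils::packageVersion("atpsim")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    checksums = as.list(vapply(paths, function(p) unname(tools::md5sum(p)), character(1)))
  )
  jsonlite::write_json(manifest, file.path(dir, paste0(prefix, "manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Per-step trace export for one trial
#'
#' Runs a single trial with the reference engine and returns (or writes) the
#' per-step critic and actor trajectories — useful for inspecting value
#' build-up, prediction errors and node dynamics.
#'
#' @param state model state (e.g. from `run_experiment(..., keep_state = TRUE)`
#'   or a fresh [atp_state()]).
#' @param stimulus,p,correct_resp,extinction,guess_p1 trial settings, as in
#'   [run_trial_r()].
#' @param cfg model configuration.
#' @param file optional CSV path.
#' @return the per-step data frame, invisibly if `file` is given.
#' @export
trial_trace <- function(state, stimulus, p, correct_resp, extinction = FALSE,
                        guess_p1 = 0.5, cfg = atp_config(), file = NULL) {
  out <- run_trial_r(state, stimulus, p, correct_resp, extinction, guess_p1,
                     cfg, detail = TRUE)
  if (is.null(file)) return(out$detail)
  utils::write.csv(out$detail, file, row.names = FALSE)
  invisible(out$detail)
}
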