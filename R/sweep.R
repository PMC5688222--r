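#' Acquisition/extinction PREE indices for one experiment batch
#'
#' The acquisition index is computed on the last acquisition block; the
#' extinction index on the first `extinction_blocks` extinction blocks
#' (component means over runs first, then the index).
#'
#' @param result an `atp_result`.
#' @param extinction_blocks extinction blocks entering the extinction window.
#' @return named numeric vector `c(acquisition, extinction)`.
#' @export
experiment_pree <- function(result, extinction_blocks = 1:3) {
  bl <- result$blocks
  last_acq <- max(bl$block[bl$phase == "acquisition"])
  acq <- phase_means(bl, "acquisition", last_acq)
  ext <- phase_means(bl, "extinction", extinction_blocks)
  # stimulus 1 is the continuous / high-density component in all bundled specs
  comp <- result$spec$component
  acq_i <- pree_index(mean(acq[[paste0("mean_correct_", comp[1])]]),
                      mean(acq[[paste0("mean_correct_", comp[2])]]))
  ext_i <- pree_index(mean(ext[[paste0("mean_correct_", comp[1])]]),
                      mean(ext[[paste0("mean_correct_", comp[2])]]))
  c(acquisition = acq_i, extinction = ext_i)
}

#' Lesion comparison across model variants
#'
#' Runs a protocol under the full two-process model, the S-R-lesioned variant
#' (expectancy mediation only) and the E-R-lesioned variant (plain
#' actor-critic), and tabulates the acquisition- and extinction-phase PREE
#' indices per variant.
#'
#' @param spec protocol (name or [protocol_spec()]).
#' @param cfg base configuration; lesion flags are overridden per variant.
#' @param runs,seed_base batch settings (defaults from the protocol).
#' @param variants subset of `c("atp", "amt", "actor_critic")`.
#' @param extinction_blocks window for the extinction index.
#' @return data frame with `model`, `acquisition_index`, `extinction_index`.
#' @export
lesion_comparison <- function(spec, cfg = atp_config(), runs = NULL,
                              seed_base = NULL,
                              variants = c("atp", "amt", "actor_critic"),
                              extinction_blocks = 1:3) {
  variants <- match.arg(variants, several.ok = TRUE)
  if (is.character(spec)) spec <- bundled_protocol(spec)
  one <- function(model) {
    cfg2 <- cfg
    cfg2$lesion$s_r <- model == "amt"
    cfg2$lesion$e_r <- model == "actor_critic"
    res <- run_experiment(spec, cfg2, runs = runs, seed_base = seed_base)
    idx <- experiment_pree(res, extinction_blocks)
    data.frame(model = model, acquisition_index = idx[["acquisition"]],
               extinction_index = idx[["extinction"]])
  }
  out <- do.call(rbind, lapply(variants, one))
  rownames(out) <- NULL
  out
}

#' Learning-rate sensitivity sweep
#'
#' Probes the S-R and omission-critic learning-rate plane while the E-R and
#' magnitude-critic rates stay fixed (0.06 by default): for each
#' `(beta_sr, beta_o)` cell the within-subjects two-lever protocol is run at
#' reduced batch size and the acquisition- and extinction-phase PREE indices
#' recorded. Cells are classified `"PREE"` (extinction index < 0) or
#' `"RPREE"` (> 0).
#'
#' @param spec protocol (name or [protocol_spec()]); default `"ko_expl"`.
#' @param beta_sr_values,beta_o_values grid axes.
#' @param n_seeds runs per cell.
#' @param seed_base seed of the first run of every cell.
#' @param cfg base configuration (fixed rates live here).
#' @param extinction_blocks window for the extinction index.
#' @return data frame of class `atp_sweep` with `beta_sr`, `beta_o`,
#'   `acquisition_index`, `extinction_index`, `classification`.
#' @export
sensitivity_sweep <- function(spec = "ko_expl",
                              beta_sr_values = c(0.25, 0.3, 0.35, 0.4),
                              beta_o_values = c(0.02, 0.04, 0.3, 0.5),
                              n_seeds = 10L, seed_base = 1L,
                              cfg = atp_config(), extinction_blocks = 1:3) {
  if (!length(beta_sr_values) || !length(beta_o_values))
    stop("sweep axes must be non-empty", call. = FALSE)
  if (is.character(spec)) spec <- bundled_protocol(spec)
  grid <- expand.grid(beta_sr = beta_sr_values, beta_o = beta_o_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg2 <- cfg
    cfg2$actor$beta_sr <- grid$beta_sr[i]
    cfg2$critic$beta_o <- grid$beta_o[i]
    res <- run_experiment(spec, cfg2, runs = n_seeds, seed_base = seed_base)
    idx <- experiment_pree(res, extinction_blocks)
    data.frame(beta_sr = grid$beta_sr[i], beta_o = grid$beta_o[i],
               acquisition_index = idx[["acquisition"]],
               extinction_index = idx[["extinction"]],
               classification = if (is.na(idx[["extinction"]])) NA_character_
                                else if (idx[["extinction"]] < 0) "PREE"
                                else "RPREE")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("atp_sweep", class(out))
  out
}
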