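# Small fixtures built in code: a shortened two-lever protocol for fast tests
# and a default configuration shared across files.

tiny_two_lever <- function(acq = 40L, ext = 20L, n_runs = 2L, seed_base = 7L) {
  protocol_spec("tiny_two_lever", "two_lever", p = c(1, 0.5),
                correct = c(1L, 2L), component = c("CRF", "PRF"),
                phases = list(
                  list(name = "acquisition", trials = acq, block_size = 20L,
                       extinction = FALSE),
                  list(name = "extinction", trials = ext, block_size = 10L,
                       extinction = TRUE)),
                n_runs = n_runs, seed_base = seed_base)
}

fresh_cfg <- function(...) atp_config(...)
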