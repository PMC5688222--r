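# Behavioural signatures of the full model at small scale; the full-scale
# (50-run) versions of the headline effects live in test-acceptance.R.

test_that("reward expectancy extinguishes with diminishing per-block decrements", {
  res <- run_experiment("ko_expl", runs = 10, seed_base = 1)
  ext <- res$trials[res$trials$phase == "extinction" &
                      res$trials$component == "CRF", ]
  rew_by_block <- tapply(ext$rew_dec, ext$block, mean)
  expect_true(all(diff(rew_by_block) < 0))          # decays toward 0
  decr <- -diff(rew_by_block)
  expect_true(all(diff(decr) < 0))                  # asymptotic profile
  expect_lt(rew_by_block[4], 0.02)
})

test_that("acquisition ordering: continuous reinforcement learns faster and ends higher", {
  res <- run_experiment("ko_expl", runs = 10, seed_base = 1)
  sm <- block_summary(res$blocks)
  acq <- sm[sm$phase == "acquisition", ]
  crf <- acq$mean[acq$component == "CRF"]
  prf <- acq$mean[acq$component == "PRF"]
  expect_true(all(crf[1:3] >= prf[1:3]))
  expect_gte(crf[6], prf[6])
})

test_that("ablating mutual inhibition leaves both expectancies high and breaks mediation", {
  cfg <- fresh_cfg(ablate = list(mutual_inhibition = TRUE))
  res <- run_experiment("ko_expl", cfg, runs = 10, seed_base = 1)
  sm <- block_summary(res$blocks)
  a6 <- sm[sm$phase == "acquisition" & sm$block == 6, ]
  expect_lte(a6$mean[a6$component == "PRF"], 0.60)
  late <- res$trials[res$trials$phase == "acquisition" &
                       res$trials$block >= 5 &
                       res$trials$component == "PRF", ]
  expect_gt(mean(late$rew_dec), 0.5)
  expect_gt(mean(late$om_dec), 0.5)
})

test_that("the critic retains magnitude across extinction (substrate of savings)", {
  spec <- protocol_spec(
    "retention", "two_lever", p = c(1, 1), correct = c(1L, 2L),
    component = c("A", "B"),
    phases = list(
      list(name = "acquisition", trials = 120L, block_size = 40L, extinction = FALSE),
      list(name = "extinction", trials = 60L, block_size = 10L, extinction = TRUE)),
    n_runs = 5L, seed_base = 1L)
  res <- run_experiment(spec, runs = 5, seed_base = 1, keep_state = TRUE)
  for (st in res$states) {
    # magnitude value one step before the reinforcer stays at its asymptote
    expect_lt(abs(clamp01(st$theta_m[48, 1]) - 0.1), 0.01)
    # while the omission value has saturated
    expect_lt(abs(clamp01(st$theta_o[48, 1]) - 0.1), 0.02)
  }
})
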