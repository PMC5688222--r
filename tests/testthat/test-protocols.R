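test_that("trial sequences are balanced, run-capped and reproducible", {
  set.seed(1)
  for (rep in 1:20) {
    s <- generate_trial_sequence(240, 40, 3)
    expect_equal(length(s), 240)
    expect_lte(max(rle(s)$lengths), 3)      # includes block boundaries
    for (b in 1:6) {
      blk <- s[((b - 1) * 40 + 1):(b * 40)]
      expect_equal(sum(blk == 1), 20)       # exact within-block balance
    }
  }
  set.seed(5); a <- generate_trial_sequence(80, 10)
  set.seed(5); b <- generate_trial_sequence(80, 10)
  expect_identical(a, b)
  expect_error(generate_trial_sequence(30, 7), "multiple")
  expect_error(generate_trial_sequence(40, 10, max_same = 0), "max_same")
})

test_that("bundled protocols encode the two experimental designs", {
  ko <- bundled_protocol("ko_expl")
  expect_equal(ko$p, c(1, 0.5))
  expect_equal(ko$correct, c(1L, 2L))
  expect_equal(ko$guess_p1, 0.5)
  expect_equal(sapply(ko$phases, `[[`, "trials"), c(240L, 40L))
  expect_equal(sapply(ko$phases, `[[`, "block_size"), c(40L, 10L))
  sv <- bundled_protocol("svartdal_multi")
  expect_equal(sv$p, c(0.8, 0.4))
  expect_equal(sv$correct, c(1L, 1L))      # single rewarded response
  expect_equal(sv$guess_p1, 0.25)          # four-permutation abstraction
  expect_equal(sapply(sv$phases, `[[`, "trials"), c(180L, 40L))
  expect_equal(bundled_protocol("svartdal_low")$p, c(0.4, 0.4))
  expect_error(bundled_protocol("nope"), "valid names")
  expect_error(protocol_spec("x", "two_lever", p = c(1, 2), correct = c(1, 2),
                             phases = list(list(name = "a", trials = 10L,
                                                block_size = 2L))),
               "probabilities")
})

test_that("reinforcement follows the schedule and extinction withholds reward", {
  spec <- tiny_two_lever(acq = 40, ext = 20, n_runs = 4)
  res <- run_experiment(spec, runs = 4, seed_base = 11)
  tr <- res$trials
  expect_equal(nrow(tr), 4 * 60)
  # extinction trials are never rewarded
  expect_false(any(tr$rewarded[tr$phase == "extinction"]))
  # reward implies a correct response
  expect_true(all(tr$correct[tr$rewarded]))
  # CRF: every correct response during acquisition is rewarded
  crf <- tr[tr$phase == "acquisition" & tr$stimulus == 1 & tr$correct, ]
  expect_true(all(crf$rewarded))
})

test_that("partial reinforcement delivers rewards at the scheduled rate", {
  res <- run_experiment("ko_prf", runs = 10, seed_base = 3)
  acq <- res$trials[res$trials$phase == "acquisition" & res$trials$correct, ]
  expect_gt(nrow(acq), 1000)
  expect_equal(mean(acq$rewarded), 0.5, tolerance = 0.05)
})

test_that("batches are deterministic and lesions freeze their weights at zero", {
  spec <- tiny_two_lever()
  a <- run_experiment(spec, runs = 2, seed_base = 5)
  b <- run_experiment(spec, runs = 2, seed_base = 5)
  expect_identical(a$trials, b$trials)
  cfg <- fresh_cfg(lesion = list(e_r = TRUE))
  res <- run_experiment(spec, cfg, runs = 2, seed_base = 5, keep_state = TRUE)
  for (st in res$states) {
    expect_equal(unname(st$omega["Om", ]), c(0, 0))
    expect_equal(unname(st$omega["Rew", ]), c(0, 0))
  }
  cfg2 <- fresh_cfg(lesion = list(s_r = TRUE))
  res2 <- run_experiment(spec, cfg2, runs = 2, seed_base = 5, keep_state = TRUE)
  for (st in res2$states) expect_equal(unname(st$omega["S1", ]), c(0, 0))
  # identical trial sequences across variants: lesioning does not perturb
  # the random stream
  expect_identical(res$trials$stimulus, a$trials$stimulus)
})

test_that("block accounting gives per-run proportions and across-run summaries", {
  spec <- tiny_two_lever(n_runs = 3)
  res <- run_experiment(spec, runs = 3, seed_base = 2)
  bl <- res$blocks
  expect_true(all(bl$prop_correct >= 0 & bl$prop_correct <= 1))
  expect_true(all(bl$n[bl$phase == "acquisition"] == 10L))  # 20-trial blocks, balanced
  sm <- block_summary(bl)
  expect_true(all(c("mean", "sem", "ci_lo", "ci_hi") %in% names(sm)))
  one <- bl[bl$phase == "extinction" & bl$block == 1 & bl$stimulus == 1, ]
  row <- sm[sm$phase == "extinction" & sm$block == 1 & sm$stimulus == 1, ]
  expect_equal(row$mean, mean(one$prop_correct))
  expect_equal(row$sem, sd(one$prop_correct) / sqrt(3))
})
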