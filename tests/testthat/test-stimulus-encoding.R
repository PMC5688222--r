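test_that("trace coefficients follow the printed formulas", {
  co <- trace_coefficients(kappa = 9.6, tau = 10, dt = 1)
  expect_equal(co$gamma, 0.9)
  expect_equal(co$lambda, 1 - (1 - 1 / 9.6) / (1 - 1 / 10), tolerance = 1e-12)
  expect_equal(co$lambda, 0.00462962962962965, tolerance = 1e-10)
  expect_equal(co$decay, co$lambda * co$gamma)
  # kappa = tau makes the numerator equal the denominator
  expect_equal(trace_coefficients(kappa = 10, tau = 10)$lambda, 0)
  expect_error(trace_coefficients(tau = 1, dt = 1), "dt")
  expect_error(trace_coefficients(kappa = 0.5, dt = 1), "kappa")
})

test_that("the CSC is an exact tapped delay line", {
  cfg <- fresh_cfg()
  # cue onset: unit 1 of the presented stimulus fires, nothing else
  phi <- csc_activation(25, 1, cfg)
  expect_equal(phi[1, 1], 1)
  expect_equal(sum(phi), 1)
  # pre-onset: all units silent
  expect_equal(sum(csc_activation(24, 1, cfg)), 0)
  # single active unit at every post-onset step; units fire in order
  fired <- sapply(25:100, function(t) {
    p <- csc_activation(t, 2, cfg)
    expect_equal(sum(p[, 1]), 0)       # non-presented stimulus silent
    expect_equal(sum(p[, 2]), 1)
    which(p[, 2] == 1)
  })
  expect_equal(fired, seq_along(fired))
  # each unit fires at exactly one timestep over the trial
  expect_equal(sort(unique(fired)), fired)
  expect_error(csc_activation(30, 3, cfg), "protocol error")
})

test_that("eligibility traces are set at onset and decay geometrically", {
  cfg <- fresh_cfg()
  co <- trace_coefficients(cfg$critic$kappa, cfg$critic$tau, cfg$trial$dt)
  tr <- new_traces(cfg)
  tr <- update_traces(tr, 25, 1, cfg)
  expect_equal(tr[1, 1], 1)
  tr <- update_traces(tr, 26, 1, cfg)
  expect_equal(tr[1, 1], co$decay, tolerance = 1e-15)
  expect_equal(co$decay, 0.0041666666667, tolerance = 1e-9)
  # iterative update matches the closed form (decay^k) for k <= 75
  for (t in 27:100) tr <- update_traces(tr, t, 1, cfg)
  ks <- 75:1
  expect_equal(tr[1:75, 1], co$decay^ks, tolerance = 1e-12)
  # traces are strictly decreasing after firing and bounded below by 0
  expect_true(all(tr >= 0 & tr <= 1))
})

test_that("the literal reward-onset trace reading is available behind a flag", {
  cfg <- fresh_cfg(critic = list(trace_mode = "reward_onset"))
  tr <- new_traces(cfg)
  for (t in 25:71) tr <- update_traces(tr, t, 1, cfg)
  # before reinforcer onset every fired unit is pinned at 1
  expect_equal(tr[1:47, 1], rep(1, 47))
  tr <- update_traces(tr, 72, 1, cfg)
  co <- trace_coefficients(cfg$critic$kappa, cfg$critic$tau, cfg$trial$dt)
  expect_equal(tr[1, 1], co$decay)
})
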