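test_that("sigmoid transfer has midpoint, saturation and printed arithmetic", {
  expect_equal(sigmoid(0.7, 3, 0.7), 0.5)
  expect_equal(sigmoid(1e4, 1, 0), 1)
  expect_equal(sigmoid(1, beta = 2), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_error(sigmoid(0, beta = -1), "positive")
})

test_that("node dynamics follow the backward-Euler recursion exactly", {
  # fixed point at the resting level with no input or self-excitation
  expect_equal(step_node(-1, 0, C = 0, h = -1), -1)
  # one Euler step from 0 with h = -1, tau = 10
  expect_equal(step_node(0, 0, tau = 10, h = -1, C = 0), -0.1)
  # convergence to h + I under constant input
  u <- 0
  for (i in 1:400) u <- step_node(u, I = 2, tau = 10, h = -1, C = 0)
  expect_equal(u, 1, tolerance = 1e-8)
  # oracle: independently coded recursion on a random input stream
  set.seed(1)
  I <- rnorm(200)
  u1 <- u2 <- -0.3
  for (i in seq_along(I)) {
    u1 <- step_node(u1, I[i], tau = 7, h = -0.5, C = 1.2, beta = 4, dt = 1)
    u2 <- u2 + (1 / 7) * (-u2 - 0.5 + 1.2 / (1 + exp(-4 * u2)) + I[i])
    expect_equal(u1, u2, tolerance = 1e-12)
  }
})

test_that("expectancies implement rectified mutual inhibition on the value readouts", {
  cfg <- fresh_cfg()
  meta <- meta_params(cfg)
  # naive network, no value: subtraction cancels exactly, Rew rectifies to 0
  e0 <- compute_expectancies(0, 0, meta, cfg)
  expect_equal(e0$rew, 0)
  l0 <- sigmoid(0, meta[["beta_vo"]], meta[["th_vo"]])
  expect_equal(e0$om, sigmoid(l0 - 0, cfg$meta$beta_om, cfg$meta$th_om))
  # sharp classifiers: high-magnitude/low-omission corner
  sharp <- c(beta_vm = 20, th_vm = 0.3, beta_vo = 20, th_vo = 0.3)
  e1 <- compute_expectancies(0.09, 0.001, sharp, cfg)
  lm <- sigmoid(0.9, 20, 0.3); lo <- sigmoid(0.01, 20, 0.3)
  expect_equal(e1$rew, lm - lo, tolerance = 1e-12)
  expect_lt(e1$om, 0.05)
  # omission corner: omission expectancy wins, reward rectified to zero
  e2 <- compute_expectancies(0.09, 0.09, sharp, cfg)
  expect_equal(e2$rew, 0)
  expect_gt(e2$om, 0.8)
})

test_that("meta-parameters sharpen congruently and clamp at their bounds", {
  cfg <- fresh_cfg()
  meta <- meta_params(cfg)
  expect_equal(update_meta_params(meta, 0, 1, cfg), meta)
  expect_equal(update_meta_params(meta, 0.5, 0, cfg), meta)   # division guard
  up <- update_meta_params(meta, 0.9, 1, cfg)
  # positive omission PE: omission slope up, omission threshold down
  expect_gt(up[["beta_vo"]], meta[["beta_vo"]])
  expect_lt(up[["th_vo"]], meta[["th_vo"]])
  expect_equal(up[["beta_vm"]], meta[["beta_vm"]])  # rectified: reward side inert
  dn <- update_meta_params(meta, -0.9, 1, cfg)
  expect_gt(dn[["beta_vm"]], meta[["beta_vm"]])
  expect_lt(dn[["th_vm"]], meta[["th_vm"]])
  # clamping at the upper slope bound
  atmax <- c(beta_vm = 4, th_vm = 0.5, beta_vo = cfg$meta$slope_max, th_vo = 0.5)
  expect_equal(update_meta_params(atmax, 5, 1, cfg)[["beta_vo"]],
               cfg$meta$slope_max)
  # the signed-linear variant moves both sides in opposite directions
  cfg2 <- fresh_cfg(meta = list(rectified = FALSE))
  mid <- c(beta_vm = 10, th_vm = 0.5, beta_vo = 10, th_vo = 0.5)
  lin <- update_meta_params(mid, 0.5, 1, cfg2)
  expect_equal(lin[["beta_vo"]] - mid[["beta_vo"]], 0.5 / cfg2$meta$C_j)
  expect_equal(lin[["beta_vm"]] - mid[["beta_vm"]], -0.5 / cfg2$meta$C_j)
})

test_that("the linear Hebbian association update follows the printed arithmetic", {
  om <- matrix(0, 2, 2)
  expect_equal(update_association_weights(om, c(0, 0), c(1, 1), 1, 0.06), om)
  up <- update_association_weights(matrix(0, 1, 1), 1, 1, 1, 0.06)
  expect_equal(up[1, 1], 0.06)
  dn <- update_association_weights(matrix(0.5, 1, 1), 1, 1, -1, 0.06)
  expect_equal(dn[1, 1], 0.44)   # negative error unlearns
  expect_error(update_association_weights(om, c(1, 1), c(1, 1), 1, 1.5),
               "learning rate")
})

test_that("response selection uses argmax above threshold and calibrated guesses below", {
  expect_equal(select_response(0.9, 0.2, threshold = 0.5, u = 0.99)$response, 1L)
  expect_true(select_response(0.9, 0.2, threshold = 0.5, u = 0.1)$driven)
  # exact ties break on the supplied draw
  expect_equal(select_response(0.7, 0.7, threshold = 0.5, u = 0.9)$response, 2L)
  # undriven guesses: two-lever uniform, single-rule at 0.25
  set.seed(99)
  g_two <- replicate(4000, select_response(0.1, 0.1, guess_p1 = 0.5)$response)
  g_one <- replicate(4000, select_response(0.1, 0.1, guess_p1 = 0.25)$response)
  expect_equal(mean(g_two == 1), 0.5, tolerance = 0.04)
  expect_equal(mean(g_one == 1), 0.25, tolerance = 0.04)
  expect_false(select_response(0.1, 0.1, u = 0.9)$driven)
})
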