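test_that("the PREE index has the printed sign convention and antisymmetry", {
  expect_equal(pree_index(0.8, 0.8), 0)
  expect_equal(pree_index(0.8, 0.4), 1 / 3)
  expect_equal(pree_index(0.3, 0.6), -1 / 3)
  # antisymmetric under swapping the components
  set.seed(2)
  a <- runif(20); b <- runif(20)
  expect_equal(pree_index(a, b), -pree_index(b, a))
  expect_warning(out <- pree_index(0, 0), "undefined")
  expect_true(is.na(out))
})

test_that("log-baseline curves behave like logs", {
  expect_equal(log_baseline_curve(0.8, 0.8), 0)
  expect_equal(log_baseline_curve(0.4, 0.8), log(0.5))
  expect_equal(log_baseline_curve(0.4, 0.8, base = 10), log10(0.5))
  p <- c(0.8, 0.6, 0.4, 0.2)
  expect_true(all(diff(log_baseline_curve(p, 0.9)) < 0))
  expect_equal(log_baseline_curve(0, 0.5, eps = 1e-3), log(1e-3 / 0.5))
  expect_error(log_baseline_curve(0.5, 0), "baseline")
  expect_error(log_baseline_curve(-0.1, 0.5), "non-negative")
})

test_that("paired t agrees with the closed-form statistic and flags degeneracy", {
  set.seed(7)
  for (i in 1:5) {
    a <- rnorm(30, 0.6, 0.1); b <- rnorm(30, 0.55, 0.1)
    res <- paired_ttest(a, b)
    d <- a - b
    t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
    p_oracle <- 2 * pt(-abs(t_oracle), length(d) - 1)
    expect_equal(res$t, t_oracle, tolerance = 1e-10)
    expect_equal(res$p, p_oracle, tolerance = 1e-10)
    expect_equal(res$df, length(d) - 1)
  }
  same <- c(0.3, 0.5, 0.7)
  expect_equal(paired_ttest(same, same)$t, 0)
  degen <- paired_ttest(c(0, 0, 0), c(1, 1, 1))
  expect_true(degen$degenerate)
  expect_error(paired_ttest(1:3, 1:4), "length")
  expect_error(paired_ttest(1, 2), "two pairs")
})

test_that("mixed ANOVA matches an independent sums-of-squares oracle", {
  set.seed(11)
  n <- 20; conds <- c("A", "B", "C")
  d <- expand.grid(run = 1:n, condition = conds, component = c("x", "y"))
  d$run <- paste(d$condition, d$run)
  eff <- c(A = 0, B = 0.05, C = -0.04)
  d$mean_correct <- 0.6 + eff[as.character(d$condition)] +
    ifelse(d$component == "x", 0.03, -0.03) + rnorm(nrow(d), 0, 0.08)
  out <- mixed_anova(d)
  # oracle: textbook partitioning for one between and one within factor
  y <- d$mean_correct
  g <- mean(y)
  cellsub <- tapply(y, d$run, mean)                 # subject means
  bmeans <- tapply(y, d$condition, mean)
  wmeans <- tapply(y, d$component, mean)
  bw <- tapply(y, interaction(d$condition, d$component), mean)
  k <- 2                                            # within levels
  ss_between <- k * n * sum((bmeans - g)^2)
  ss_subj <- k * sum((cellsub - g)^2)
  ss_err_b <- ss_subj - ss_between
  ss_within <- 3 * n * sum((wmeans - g)^2)
  ss_cells <- n * sum((bw - g)^2)
  ss_int <- ss_cells - ss_between - ss_within
  ss_tot <- sum((y - g)^2)
  ss_err_w <- ss_tot - ss_subj - ss_within - ss_int
  df_err_b <- 3 * n - 3
  df_err_w <- (3 * n - 3) * (k - 1)
  F_b <- (ss_between / 2) / (ss_err_b / df_err_b)
  F_w <- (ss_within / 1) / (ss_err_w / df_err_w)
  F_i <- (ss_int / 2) / (ss_err_w / df_err_w)
  expect_equal(out$F[out$effect == "between"], F_b, tolerance = 1e-8)
  expect_equal(out$F[out$effect == "within"], F_w, tolerance = 1e-8)
  expect_equal(out$F[out$effect == "interaction"], F_i, tolerance = 1e-8)
  expect_equal(out$df1, c(2, 1, 2))
  expect_equal(out$df2, c(df_err_b, df_err_w, df_err_w))
  expect_equal(out$eta_p2[out$effect == "between"],
               ss_between / (ss_between + ss_err_b), tolerance = 1e-8)
})

test_that("mixed ANOVA degrees of freedom match the balanced three-condition design", {
  set.seed(3)
  n <- 50
  d <- expand.grid(run = 1:n, condition = c("A", "B", "C"),
                   component = c("x", "y"))
  d$run <- paste(d$condition, d$run)
  d$mean_correct <- runif(nrow(d))
  out <- mixed_anova(d)
  expect_equal(out$df1[out$effect == "between"], 2)
  expect_equal(out$df2[out$effect == "between"], 147)
  expect_equal(out$df1[out$effect == "within"], 1)
  expect_equal(out$df2[out$effect == "within"], 147)
  # zero between-condition variance gives a near-null between effect
  d$mean_correct <- rep(runif(2 * n), 3)
  d$run <- paste(d$condition, rep(1:n, 6))    # keep runs nested
  out0 <- mixed_anova(d)
  expect_lt(out0$F[out0$effect == "between"], 1e-10)
  # unbalanced designs are rejected
  expect_error(mixed_anova(d[-1, ]), "balanced")
})
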