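test_that("the gamma HRF is causal, unit-peak and transient", {
  tg <- seq(0, 32, by = 0.1)
  h <- gamma_hrf(tg)
  expect_equal(h[1], 0)                       # nothing before the stimulus
  expect_true(all(h >= 0))
  expect_equal(max(h), 1, tolerance = 1e-4)   # unit peak (grid misses it slightly)
  t_peak <- tg[which.max(h)]
  expect_gt(t_peak, 4); expect_lt(t_peak, 6)
  expect_lt(max(h[tg >= 25]), 0.01)           # back near baseline by 25 s
  expect_gt(sum(h) * 0.1, 0)                  # finite positive integral
  expect_error(gamma_hrf(tg, p = -1), "positive")
})

test_that("the block layout reproduces the session geometry", {
  lay <- block_layout()
  expect_equal(lay$run_dur, 420)              # 7-minute runs
  expect_equal(lay$n_volumes, 210)
  expect_length(lay$onsets, 180)
  expect_equal(sum(lay$run == 1), 60)
  # trials are back-to-back inside blocks (no ITI): gaps are 5 s or rest
  gaps <- diff(lay$onsets[lay$run == 1])
  expect_true(all(gaps %in% c(5, 5 + 30)))
})

test_that("design construction is linear and centering kills constants", {
  task <- generate_task_sequence(180, seed = 12)
  val <- valuate_sequence(task, model_params(-0.2))
  ds <- simulate_model_agent(task, -0.2, seed = 13)
  d <- build_design(val, ds$choices)
  expect_equal(colnames(d$X),
               c("run1", "run2", "run3", "risk", "reward", "entropy"))
  expect_length(d$zero_columns, 0)

  # constant modulator with mean-centering: regressor identically ~ 0
  val_const <- val
  val_const$risk[] <- 0.37
  d_const <- build_design(val_const, ds$choices)
  expect_lt(max(abs(d_const$X[, "risk"])), 1e-12)
  expect_equal(d_const$zero_columns, "risk")

  # doubling modulators doubles the (uncentered) regressor
  val2 <- val
  val2$risk <- 2 * val$risk
  d1 <- build_design(val, ds$choices, mean_center = FALSE)
  d2 <- build_design(val2, ds$choices, mean_center = FALSE)
  expect_equal(d2$X[, "risk"], 2 * d1$X[, "risk"], tolerance = 1e-12)

  # single unit impulse reproduces the sampled kernel
  lay1 <- block_layout(n_runs = 1, blocks_per_run = 1, trials_per_block = 1,
                       trial_dur = 6, rest_dur = 30)
  r1 <- riskdeck:::.convolve_regressor(30, 1, lay1$run_dur, 2, gamma_hrf)
  tv <- 2 * (0:(length(r1) - 1))
  expect_equal(r1, gamma_hrf(tv - 30), tolerance = 1e-9)
})

test_that("OLS recovers noiseless betas and matches the normal equations", {
  set.seed(31)
  for (i in 1:20) {
    X <- cbind(1, matrix(rnorm(20 * 3), 20, 3))
    colnames(X) <- c("b0", "x1", "x2", "x3")
    b_true <- rnorm(4)
    y <- as.vector(X %*% b_true)
    g <- fit_glm(y, X)
    expect_lt(max(abs(g$beta - b_true)), 1e-8)
    # textbook normal-equations oracle with noise
    y2 <- y + rnorm(20)
    g2 <- fit_glm(y2, X)
    b_oracle <- solve(t(X) %*% X, t(X) %*% y2)
    expect_equal(unname(g2$beta), as.vector(b_oracle), tolerance = 1e-10)
    s2 <- sum((y2 - X %*% b_oracle)^2) / (20 - 4)
    se_oracle <- sqrt(s2 * diag(solve(t(X) %*% X)))
    expect_equal(unname(g2$se), unname(se_oracle), tolerance = 1e-10)
  }
  # rank deficiency is reported with the offending column
  Xr <- cbind(a = rnorm(10), b = rnorm(10))
  Xr <- cbind(Xr, c = Xr[, "a"] + Xr[, "b"])
  expect_error(fit_glm(rnorm(10), Xr), "rank deficient")
  expect_error(fit_glm(rnorm(5), diag(3)), "length")
})

test_that("null z-statistics are calibrated", {
  task <- generate_task_sequence(180, seed = 17)
  val <- valuate_sequence(task, model_params(-0.2))
  ds <- simulate_model_agent(task, -0.2, seed = 18)
  d <- build_design(val, ds$choices)
  X <- d$X
  XtXi <- solve(crossprod(X))
  H <- XtXi %*% t(X)
  k <- which(colnames(X) == "risk")
  df <- nrow(X) - ncol(X)
  set.seed(19)
  z <- vapply(1:500, function(j) {
    y <- rnorm(nrow(X))
    b <- H %*% y
    res <- y - X %*% b
    s2 <- sum(res^2) / df
    b[k] / sqrt(s2 * XtXi[k, k])
  }, numeric(1))
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(sd(z) - 1), 0.1)
  # cross-check the closed-form path against fit_glm on one draw
  set.seed(23)
  y <- rnorm(nrow(X))
  expect_equal(fit_glm(y, d)$z[["risk"]],
               {
                 b <- H %*% y; res <- y - X %*% b
                 unname(b[k] / sqrt(sum(res^2) / df * XtXi[k, k]))
               }, tolerance = 1e-10)
})

test_that("the group activation test is the one-sample t-test", {
  v <- c(0.42, -0.1, 0.77, 0.31, 0.05)
  g <- group_activation_test(v)
  tt <- t.test(v)
  expect_equal(g$t, unname(tt$statistic))
  expect_equal(g$p, tt$p.value)
  z0 <- group_activation_test(rep(0, 6))
  expect_equal(z0$t, 0)
  expect_equal(z0$p, 1)
  expect_error(group_activation_test(1), "at least 2")
})
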