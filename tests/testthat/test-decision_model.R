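test_that("reward prediction is the two-outcome expectation", {
  expect_equal(reward_prediction(1, 0.8, 1.0), 0.8)
  expect_equal(reward_prediction(0.5, 0.8, 1.0), -0.1)
  expect_equal(reward_prediction(0, 0.5, 0.2), -0.2)
  expect_error(reward_prediction(1.2, 1, 1), "\\[0, 1\\]")
})

test_that("risk prediction equals the brute-force two-outcome variance", {
  # oracle: E[(r - E r)^2] over the win/loss outcomes
  brute_var <- function(p, W, L) {
    er <- p * W + (1 - p) * (-L)
    p * (W - er)^2 + (1 - p) * (-L - er)^2
  }
  for (p in seq(0, 1, by = 0.05))
    expect_lt(abs(risk_prediction(p, 0.8, 1.0) - brute_var(p, 0.8, 1.0)), 1e-12)
  expect_equal(risk_prediction(0, 2, 3), 0)
  expect_equal(risk_prediction(1, 2, 3), 0)
  expect_equal(risk_prediction(0.5, 0.8, 1.0), 0.81)
  # maximum at p = 0.5
  g <- risk_prediction(seq(0, 1, 0.05), 1, 1)
  expect_equal(which.max(g), 11L)
})

test_that("utility is linear in risk with slope l", {
  expect_equal(utility(-0.1, 0.81, -0.5), -0.505)
  expect_equal(utility(0.3, 0, 0.9), 0.3)       # zero risk: l irrelevant
  expect_equal(utility(c(1, 2), c(0, 0), 0.5), c(1, 2))
  expect_error(utility(0, -1, 0), "non-negative")
})

test_that("softmax probabilities are normalized, shift-invariant and correct", {
  expect_equal(choice_probabilities(rep(2.3, 4)), rep(0.25, 4))
  u <- c(0.4, -0.3, 0.1, 0.05)
  expect_equal(choice_probabilities(u), choice_probabilities(u + 17))
  expect_equal(choice_probabilities(c(1, 0, 0, 0))[1], exp(1) / (exp(1) + 3))
  expect_equal(sum(choice_probabilities(u)), 1)
  # overflow safety
  expect_equal(sum(choice_probabilities(c(900, 800, 700, 600))), 1)
  expect_error(choice_probabilities(c(Inf, 0, 0, 0)), "finite")
  # matrix form matches the oracle row-wise
  m <- rbind(u, c(0, 0, 0, 0), c(-1, 2, 0.5, 0.5))
  pm <- choice_probabilities(m)
  for (i in 1:3) expect_equal(unname(pm[i, ]), oracle_softmax(m[i, ]))
})

test_that("trial entropy has the closed-form landmarks", {
  expect_equal(trial_entropy(rep(0.25, 4)), log(4))
  expect_equal(trial_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(trial_entropy(c(0.5, 0.5, 0, 0)), log(2))
  expect_error(trial_entropy(c(-0.1, 0.6, 0.3, 0.2)), "non-negative")
})

test_that("trial valuation composes the components correctly", {
  # same value on payoff-identical decks gives the same utility (symmetry)
  tv <- valuate_trial(c(50, 55, 50, 55), params = model_params(-0.3))
  tv_swap <- valuate_trial(c(55, 50, 55, 50), params = model_params(-0.3))
  expect_equal(tv$utility[["A"]], tv_swap$utility[["B"]])
  expect_equal(tv$utility[["C"]], tv_swap$utility[["D"]])
  expect_equal(sum(tv$probabilities), 1)

  # l = 0, values (100, 0, 100, 0): utility order A > C > D > B
  tv0 <- valuate_trial(c(100, 0, 100, 0), params = model_params(0))
  expect_equal(unname(tv0$utility),
               c(100 / 125, -1, 50 / 125, -25 / 125))
  expect_equal(names(sort(tv0$utility, decreasing = TRUE)),
               c("A", "C", "D", "B"))
  # a dominated trial is easier than maximal entropy
  expect_lt(tv0$entropy, log(4))

  # matrix path agrees with the scalar path and the independent oracle
  task <- tiny_task(8)
  val <- valuate_sequence(task, model_params(-0.4))
  for (t in c(1, 5, 8)) {
    expect_equal(unname(val$probabilities[t, ]),
                 unname(oracle_trial_probs(task$values[t, ], -0.4)))
    one <- valuate_trial(task$values[t, ], params = model_params(-0.4))
    expect_equal(val$utility[t, ], one$utility)
    expect_equal(val$entropy[t], one$entropy)
  }
})

test_that("probabilities are equivariant under deck permutation", {
  task <- tiny_task(6)
  val <- valuate_sequence(task, model_params(0.3))
  # swapping decks A and B (same payoffs) swaps their probabilities
  task2 <- task
  task2$values <- task$values[, c("B", "A", "C", "D")]
  colnames(task2$values) <- c("A", "B", "C", "D")
  val2 <- valuate_sequence(task2, model_params(0.3))
  expect_equal(unname(val2$probabilities[, 1]), unname(val$probabilities[, 2]))
  expect_equal(unname(val2$probabilities[, 2]), unname(val$probabilities[, 1]))
})

test_that("increasing l favours the higher-variance deck", {
  task <- tiny_task(20, seed = 11)
  lgrid <- seq(-1, 1, by = 0.25)
  probs <- lapply(lgrid, function(l)
    valuate_sequence(task, model_params(l)))
  for (t in 1:20) {
    vr <- probs[[1]]$risk[t, ]
    hi <- which.max(vr)
    if (max(vr) - min(vr) < 1e-9) next
    p_hi <- vapply(probs, function(v) v$probabilities[t, hi], numeric(1))
    expect_true(all(diff(p_hi) >= -1e-12))
  }
})

test_that("tidy valuation export has one row per trial and deck", {
  task <- tiny_task(5)
  df <- as.data.frame(valuate_sequence(task))
  expect_equal(nrow(df), 20)
  expect_setequal(unique(df$deck), c("A", "B", "C", "D"))
  expect_true(all(abs(tapply(df$probability, df$trial, sum) - 1) < 1e-12))
})
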