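test_that("random agents choose each deck uniformly and reproducibly", {
  task <- generate_task_sequence(180, seed = 3)
  set.seed(99)
  counts <- table(factor(unlist(lapply(1:50, function(j)
    simulate_random_agent(task)$choices)), levels = 1:4))
  chi <- stats::chisq.test(counts)
  expect_gt(chi$p.value, 0.001)
  a <- simulate_random_agent(task, seed = 7)
  b <- simulate_random_agent(task, seed = 7)
  expect_identical(a$choices, b$choices)
})

test_that("model agents track the softmax probabilities", {
  task <- fixed_task(c(100, 0, 50, 45))
  # replicate the single trial many times via repeated agents
  probs <- oracle_trial_probs(c(100, 0, 50, 45), l = -0.4)
  set.seed(4)
  picks <- vapply(1:4000, function(j)
    simulate_model_agent(task, -0.4)$choices[1], integer(1))
  freq <- tabulate(picks, 4) / 4000
  expect_lt(max(abs(freq - probs)), 0.03)

  # extreme utilities give near-deterministic choices
  ex <- fixed_task(c(100, 0, 5, 0))
  exv <- valuate_trial(ex$values[1, ], params = model_params(1,
                                                             payoff_scale = 10))
  expect_gt(max(exv$probabilities), 0.99)
  expect_error(simulate_model_agent(task, 2), "\\[-1, 1\\]")
})

test_that("cohort generation hits the NS and risk-preference targets", {
  task <- generate_task_sequence(30, seed = 2)
  cfg <- cohort_config(n_subjects = 500, seed = 10)
  subjects <- generate_cohort(cfg, task)
  ns <- vapply(subjects, `[[`, numeric(1), "ns_score")
  l <- vapply(subjects, `[[`, numeric(1), "l_true")
  expect_true(all(ns == round(ns) & ns >= 0 & ns <= 34))
  expect_true(all(l >= -1 & l <= 1))
  expect_lt(abs(cor(ns, l) - 0.555), 0.1)
  expect_lt(abs(mean(ns) - 14.57), 0.6)
  expect_lt(abs(mean(l) - (-0.15)), 0.05)

  # independence when the target correlation is zero
  cfg0 <- cohort_config(n_subjects = 500, rho_ns_l = 0, seed = 11)
  s0 <- generate_cohort(cfg0, task)
  expect_lt(abs(attr(s0, "achieved_rho_ns_l")), 0.1)
})

test_that("task BOLD simulation is exactly linear at zero noise", {
  task <- generate_task_sequence(180, seed = 6)
  val <- valuate_sequence(task, model_params(-0.3))
  ds <- simulate_model_agent(task, -0.3, seed = 8)
  betas <- c(risk = 2.5, reward = -1.2, entropy = 0.7)
  sim <- simulate_task_bold(val, ds$choices, betas = betas, noise_sd = 0)
  g <- fit_glm(sim$series, sim$design)
  expect_lt(abs(g$beta[["risk"]] - 2.5), 1e-8)
  expect_lt(abs(g$beta[["reward"]] - (-1.2)), 1e-8)
  expect_lt(abs(g$beta[["entropy"]] - 0.7), 1e-8)
  # session dimensions: 3 runs x 210 volumes of a 7-minute run at TR 2
  expect_equal(length(sim$series), 3 * 210)
})

test_that("risk-beta draws reach the target correlation with NS at scale", {
  set.seed(20)
  z <- as.vector(scale(rnorm(500)))
  beta <- 2 + 2 * riskdeck:::.corr_draw(z, -0.51)
  expect_lt(abs(cor(z, beta) - (-0.51)), 0.1)
})

test_that("resting-state simulation honours correlation targets and spikes", {
  rois <- c("SMA", "r_striatum", "l_AI", "r_PI")
  ident <- diag(4); dimnames(ident) <- list(rois, rois)
  # band-limiting leaves ~70 effective df, so judge the null correlations
  # across several seeds rather than one draw
  offdiag <- unlist(lapply(1:5, function(s) {
    r0 <- simulate_resting_state(ident, noise_sd = 0, seed = 14 + s)
    cr <- cor(r0$series)
    abs(cr[upper.tri(cr)])
  }))
  expect_lt(mean(offdiag), 0.15)
  expect_lt(max(offdiag), 0.35)
  rest0 <- simulate_resting_state(ident, noise_sd = 0, seed = 14)
  expect_equal(dim(rest0$series), c(240L, 4L))

  # spikes appear in the motion table at exactly the scheduled volumes
  rest_sp <- simulate_resting_state(ident, spike_volumes = c(50, 51),
                                    seed = 15)
  fd <- framewise_displacement(rest_sp$motion)
  expect_identical(which(fd > 0.5), c(50L, 51L))

  # non-PSD target matrix is rejected
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(simulate_resting_state(bad), "positive semi-definite")
})

test_that("a generated inter-ROI correlation survives the cleaning chain", {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.5
  dimnames(R) <- list(paste0("roi", 1:4), paste0("roi", 1:4))
  zs <- vapply(1:6, function(s) {
    rest <- simulate_resting_state(R, spike_volumes = c(30, 100),
                                   seed = 200 + s)
    fc <- rsfc_pipeline(rest$series, rest$motion)
    fc$pairs$r[fc$pairs$roi_a == "roi1" & fc$pairs$roi_b == "roi2"]
  }, numeric(1))
  expect_lt(abs(mean(zs) - 0.5), 0.15)
})

test_that("cohort directories are written with one choices file per subject", {
  task <- generate_task_sequence(12, seed = 1)
  subjects <- generate_cohort(cohort_config(n_subjects = 4, seed = 2), task)
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  write_cohort(subjects, dir)
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  expect_length(list.files(dir, pattern = "^choices_"), 4)
  df <- read.csv(file.path(dir, "subjects.csv"))
  expect_equal(nrow(df), 4)
})
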