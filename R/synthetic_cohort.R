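# Synthetic cohort with known ground truth: random and softmax agents, a
# novelty-seeking (NS) score correlated with risk preference, task BOLD
# series with NS-dependent risk modulation, and resting-state series.

#' Cohort configuration
#'
#' Defaults emulate the reference study population: 30 subjects, NS scores
#' (0-34 integer scale) with mean 14.57 and SD 3.81, risk preference with
#' mean -0.15 and SD 0.27, NS-l correlation 0.555, and negative neural
#' effects (risk-beta-NS correlation -0.51; connectivity-NS correlation
#' -0.511).
#'
#' @param n_subjects cohort size.
#' @param ns_mean,ns_sd,ns_range NS score distribution (latent normal,
#'   rounded and clipped to `ns_range`).
#' @param l_mean,l_sd,l_bounds risk-preference distribution (normal, clipped
#'   to `l_bounds`).
#' @param rho_ns_l target latent correlation between NS and risk preference.
#' @param neural_effect target correlation, across subjects, between the
#'   risk-modulation amplitude of each ROI and NS.
#' @param rsfc_effect target correlation between the NS-modulated ROI-pair
#'   connectivity (Fisher z) and NS.
#' @param bold_noise_sd,bold_ar1 task-BOLD noise level and AR(1) coefficient.
#' @param rest_noise_sd white measurement noise added to resting series.
#' @param seed integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 30L, ns_mean = 14.57, ns_sd = 3.81,
                          ns_range = c(0L, 34L), l_mean = -0.15, l_sd = 0.27,
                          l_bounds = c(-1, 1), rho_ns_l = 0.555,
                          neural_effect = -0.51, rsfc_effect = -0.511,
                          bold_noise_sd = 1, bold_ar1 = 0.3,
                          rest_noise_sd = 0.3, seed = 1L) {
  stopifnot(ns_sd > 0, l_sd > 0, abs(rho_ns_l) < 1, abs(neural_effect) < 1,
            abs(rsfc_effect) < 1)
  structure(list(n_subjects = as.integer(n_subjects), ns_mean = ns_mean,
                 ns_sd = ns_sd, ns_range = ns_range, l_mean = l_mean,
                 l_sd = l_sd, l_bounds = l_bounds, rho_ns_l = rho_ns_l,
                 neural_effect = neural_effect, rsfc_effect = rsfc_effect,
                 bold_noise_sd = bold_noise_sd, bold_ar1 = bold_ar1,
                 rest_noise_sd = rest_noise_sd, seed = seed),
            class = "cohort_config")
}

#' Simulate a uniform-random agent
#'
#' Choices are uniform over the four decks, independent of the displayed
#' values; outcomes are realized under the task's payoff rule.
#'
#' @param task a `task_sequence`.
#' @param seed optional integer seed.
#' @return A `choice_dataset`.
#' @export
simulate_random_agent <- function(task, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  choice_dataset(task, sample.int(4L, task$n_trials, replace = TRUE))
}

#' Simulate a softmax model agent
#'
#' Choices are sampled from the model's softmax probabilities at risk
#' preference `l`; outcomes are realized under the payoff rule.
#'
#' @param task a `task_sequence`.
#' @param l risk preference in \[-1, 1\].
#' @param params model parameters (payoff scale; `risk_preference` ignored).
#' @param seed optional integer seed.
#' @return A `choice_dataset`.
#' @export
simulate_model_agent <- function(task, l, params = model_params(),
                                 seed = NULL) {
  if (l < -1 || l > 1) stop("l must lie in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  P <- valuate_sequence(task, model_params(l, params$payoff_scale,
                                           params$risk_as_sd))$probabilities
  u <- stats::runif(task$n_trials)
  ch <- 1L + (u > P[, 1L]) + (u > P[, 1L] + P[, 2L]) +
    (u > P[, 1L] + P[, 2L] + P[, 3L])
  choice_dataset(task, as.integer(ch))
}

# standard-normal draw with target correlation rho to the standard scores z
.corr_draw <- function(z, rho) {
  rho * z + sqrt(1 - rho^2) * stats::rnorm(length(z))
}

#' Generate a behavioural cohort
#'
#' Draws (NS, l) from a latent bivariate normal with correlation
#' `rho_ns_l`, rounds and clips NS to its integer range, clips l to its
#' bounds, and simulates each subject's 180-trial behaviour from the softmax
#' model at that subject's l. The achieved (post-discretization) sample
#' correlation is recorded; a deviation above 0.1 from the target raises a
#' warning.
#'
#' @param config a `cohort_config`.
#' @param task the shared `task_sequence`.
#' @param params model parameters used by the generating agents.
#' @return A list of subject records (`subject_id`, `ns_score`, `l_true`,
#'   `dataset`), with attribute `achieved_rho_ns_l`.
#' @export
generate_cohort <- function(config, task, params = model_params()) {
  set.seed(config$seed)
  n <- config$n_subjects
  z1 <- stats::rnorm(n)
  z2 <- .corr_draw(z1, config$rho_ns_l)
  ns <- pmin(pmax(round(config$ns_mean + config$ns_sd * z1),
                  config$ns_range[1]), config$ns_range[2])
  l <- pmin(pmax(config$l_mean + config$l_sd * z2,
                 config$l_bounds[1]), config$l_bounds[2])
  subjects <- lapply(seq_len(n), function(i) {
    list(subject_id = sprintf("sub%02d", i), ns_score = as.integer(ns[i]),
         l_true = l[i],
         dataset = simulate_model_agent(task, l[i], params))
  })
  achieved <- stats::cor(ns, l)
  if (abs(achieved - config$rho_ns_l) > 0.1 && n >= 100)
    warning(sprintf("achieved NS-l correlation %.3f deviates from target %.3f",
                    achieved, config$rho_ns_l))
  attr(subjects, "achieved_rho_ns_l") <- achieved
  subjects
}

#' Simulate a task BOLD series for one subject
#'
#' Builds the parametric design from the subject's trial valuations and
#' choices, forms series = X beta + AR(1) Gaussian noise, and returns both.
#' With `noise_sd = 0` the GLM recovers `betas` exactly.
#'
#' @param valuations the subject's `trial_valuations`.
#' @param choices the subject's choices (1-4 per trial).
#' @param betas named effect sizes `c(risk=, reward=, entropy=)`, in signal
#'   units per unit of (mean-centered, HRF-convolved) modulator.
#' @param layout a [block_layout()].
#' @param baseline run baseline level (default 100).
#' @param noise_sd innovation SD of the AR(1) noise.
#' @param ar1 AR(1) coefficient (default 0.3).
#' @param seed optional integer seed.
#' @return A list with `series` (one value per volume) and `design`.
#' @export
simulate_task_bold <- function(valuations, choices,
                               betas = c(risk = 1, reward = 1, entropy = 1),
                               layout = block_layout(), baseline = 100,
                               noise_sd = 1, ar1 = 0.3, seed = NULL) {
  design <- build_design(valuations, choices, layout)
  if (!is.null(seed)) set.seed(seed)
  b_par <- betas[c("risk", "reward", "entropy")]
  if (anyNA(b_par))
    stop("betas must be a named vector with elements risk, reward, entropy")
  b <- c(rep(baseline, layout$n_runs), b_par)
  nv <- nrow(design$X)
  noise <- if (noise_sd > 0)
    as.vector(stats::arima.sim(list(ar = ar1), nv, sd = noise_sd))
  else numeric(nv)
  list(series = as.vector(design$X %*% b) + noise, design = design)
}

#' Simulate a resting-state session for one subject
#'
#' Band-limited (0.01-0.08 Hz) Gaussian ROI series with a target inter-ROI
#' correlation structure, plus white measurement noise and a six-parameter
#' motion table that is zero except for injected displacement steps at
#' `spike_volumes` (each step moves the head by `spike_size` mm, so exactly
#' those volumes exceed an FD threshold below `spike_size`).
#'
#' @param target_corr ROI x ROI positive semi-definite correlation matrix
#'   (column names become ROI names).
#' @param n_volumes number of volumes (default 240, an 8-min scan at TR 2 s).
#' @param TR repetition time in seconds.
#' @param spike_volumes integer volumes at which motion steps occur.
#' @param spike_size displacement step in mm (default 1).
#' @param noise_sd white measurement noise SD relative to unit signal SD.
#' @param seed optional integer seed.
#' @return A list with `series` (volumes x ROIs) and `motion` (volumes x 6).
#' @export
simulate_resting_state <- function(target_corr, n_volumes = 240L, TR = 2,
                                   spike_volumes = integer(0), spike_size = 1,
                                   noise_sd = 0.3, seed = NULL) {
  R <- as.matrix(target_corr)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("target correlation matrix must be positive semi-definite")
  if (!is.null(seed)) set.seed(seed)
  k <- ncol(R)
  z <- matrix(stats::rnorm(n_volumes * k), n_volumes, k)
  z <- bandpass(z, 0.01, 0.08, TR)
  z <- scale(z)                          # unit variance before mixing
  U <- chol(R + diag(1e-10, k))
  y <- z %*% U + noise_sd * matrix(stats::rnorm(n_volumes * k), n_volumes, k)
  colnames(y) <- colnames(R)
  motion <- matrix(0, n_volumes, 6L,
                   dimnames = list(NULL, c("tx", "ty", "tz",
                                           "rx", "ry", "rz")))
  if (length(spike_volumes) > 0) {
    if (any(spike_volumes < 2L | spike_volumes > n_volumes))
      stop("spike_volumes must lie in 2..n_volumes")
    for (v in spike_volumes)
      motion[v:n_volumes, "tx"] <- motion[v:n_volumes, "tx"] + spike_size
  }
  list(series = y, motion = motion)
}
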