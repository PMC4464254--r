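# End-to-end study replica: cohort -> behavioural fits -> task GLM ->
# resting-state connectivity -> group statistics, from one seeded config.

RISK_ROIS <- c("SMA", "r_striatum", "l_AI", "r_PI")

#' Pipeline configuration
#'
#' One seeded configuration object driving [run_pipeline()]. Every
#' stochastic stage derives its seed from `seed`, so a run is fully
#' deterministic.
#'
#' @param cohort a [cohort_config()].
#' @param search a [search_config()] for the per-subject MLE.
#' @param params [model_params()] shared by generation and fitting.
#' @param layout a [block_layout()].
#' @param n_random_agents uniform-random agents for the goodness-of-fit
#'   comparison table (0 skips that stage).
#' @param risk_beta_mean,risk_beta_sd across-subject distribution of the
#'   risk-modulation amplitude (its correlation with NS is
#'   `cohort$neural_effect`).
#' @param rsfc_base baseline inter-ROI correlation of the resting network.
#' @param rsfc_z_sd across-subject SD of the NS-modulated pair connectivity
#'   on the Fisher-z scale.
#' @param mediation_roi ROI whose risk activation enters the mediation chain
#'   (X = activation, M = risk preference, Y = NS).
#' @param alpha family-wise alpha for all correlation families.
#' @param seed global integer seed.
#' @param out_dir optional directory; when set, [run_pipeline()] writes the
#'   report files there.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), search = search_config(),
                            params = model_params(), layout = block_layout(),
                            n_random_agents = 200L, risk_beta_mean = 2,
                            risk_beta_sd = 2, rsfc_base = 0.3,
                            rsfc_z_sd = 0.25, mediation_roi = "r_PI",
                            alpha = 0.05, seed = 1L, out_dir = NULL) {
  structure(list(cohort = cohort, search = search, params = params,
                 layout = layout, n_random_agents = as.integer(n_random_agents),
                 risk_beta_mean = risk_beta_mean, risk_beta_sd = risk_beta_sd,
                 rsfc_base = rsfc_base, rsfc_z_sd = rsfc_z_sd,
                 mediation_roi = mediation_roi, alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# NS-modulated per-subject resting correlation matrix over the four ROIs:
# the r_PI pairs carry the NS effect on the Fisher-z scale.
.rest_target_matrix <- function(base_r, z_pi_str, z_pi_ai) {
  R <- matrix(base_r, 4L, 4L, dimnames = list(RISK_ROIS, RISK_ROIS))
  diag(R) <- 1
  R["r_PI", "r_striatum"] <- R["r_striatum", "r_PI"] <- tanh(z_pi_str)
  R["r_PI", "l_AI"] <- R["l_AI", "r_PI"] <- tanh(z_pi_ai)
  R
}

#' Goodness-of-fit comparison table for two agent groups
#'
#' Mean +/- SD of the per-trial MLL, AIC, AICc and BIC for model-agent fits
#' and uniform-random-agent fits, with pooled independent-samples t-tests.
#'
#' @param fits_model,fits_random lists of `fit_result` objects.
#' @param M_model,M_random group sizes for the information-criterion
#'   convention (default the number of fits).
#' @return An object of class `fit_table` wrapping the
#'   [compare_fit_groups()] data.frame.
#' @export
make_table1 <- function(fits_model, fits_random,
                        M_model = length(fits_model),
                        M_random = length(fits_random)) {
  if (length(fits_model) == 0L || length(fits_random) == 0L)
    stop("both fit groups must be non-empty")
  cmp <- compare_fit_groups(fits_model, fits_random, M_model, M_random)
  names(cmp)[names(cmp) == "mean_a"] <- "mean_model"
  names(cmp)[names(cmp) == "sd_a"] <- "sd_model"
  names(cmp)[names(cmp) == "mean_b"] <- "mean_random"
  names(cmp)[names(cmp) == "sd_b"] <- "sd_random"
  structure(list(table = cmp, n_model = length(fits_model),
                 n_random = length(fits_random)),
            class = "fit_table")
}

#' @export
print.fit_table <- function(x, ...) {
  cat("Goodness of fit: model agents (n =", x$n_model,
      ") vs uniform-random agents (n =", x$n_random, ")\n")
  tb <- x$table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-5s %6.2f+/-%.2f  %6.2f+/-%.2f  t = %8.2f  p = %.3g\n",
                toupper(tb$statistic[i]), tb$mean_model[i], tb$sd_model[i],
                tb$mean_random[i], tb$sd_random[i], tb$t[i], tb$p[i]))
  invisible(x)
}

#' Run the full study replica
#'
#' Generates the shared task sequence and the synthetic cohort, fits the
#' risk-preference model per subject, fits uniform-random comparison agents,
#' simulates and analyses task BOLD (parametric GLM, z-transformed risk
#' effects) and resting-state data (cleaning chain, pairwise Fisher-z
#' connectivity), and computes the group statistics: NS-risk-preference
#' correlation, NS-activation correlations (Bonferroni over 4 ROIs),
#' partial correlations controlling risk preference, NS-connectivity
#' correlations (Bonferroni over 6 pairs), and the Sobel mediation chain.
#'
#' @param config a [pipeline_config()].
#' @return A report list with elements `subjects` (data.frame), `fits`,
#'   `table1`, `cor_ns_l`, `activation` (per-ROI correlation and group
#'   test), `partial` (per-ROI partial correlation), `rsfc` (per-pair
#'   correlation), `mediation`, `achieved_rho_ns_l`, `config` and `log`.
#'   Written to `config$out_dir` when set (see [write_report()]).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  log <- character(0)
  stamp <- function(stage) log <<- c(log, paste0(stage, " [seed ", seed, "]"))

  # --- task + cohort ---------------------------------------------------
  task <- generate_task_sequence(length(config$layout$onsets),
                                 seed = seed)
  stamp("task")
  ccfg <- config$cohort
  ccfg$seed <- seed + 1L
  subjects <- generate_cohort(ccfg, task, config$params)
  n <- length(subjects)
  if (n < 4L) stop("stats stage requires at least 4 subjects")
  ns <- vapply(subjects, `[[`, numeric(1), "ns_score")
  l_true <- vapply(subjects, `[[`, numeric(1), "l_true")
  stamp("cohort")

  # --- behavioural fits ------------------------------------------------
  search <- config$search
  fits <- lapply(seq_len(n), function(i) {
    search$seed <- seed + 100L + i
    fit_risk_preference(subjects[[i]]$dataset, search, config$params)
  })
  l_hat <- vapply(fits, `[[`, numeric(1), "l_hat")
  stamp("fit")

  table1 <- NULL
  if (config$n_random_agents > 0L) {
    rfits <- lapply(seq_len(config$n_random_agents), function(j) {
      search$seed <- seed + 2000L + j
      fit_risk_preference(simulate_random_agent(task, seed + 1000L + j),
                          search, config$params)
    })
    table1 <- make_table1(fits, rfits)
    stamp("table1")
  }

  # --- task BOLD + GLM -------------------------------------------------
  set.seed(seed + 3L)
  zns <- as.vector(scale(ns))
  beta_risk <- sapply(RISK_ROIS, function(r)
    config$risk_beta_mean +
      config$risk_beta_sd * .corr_draw(zns, ccfg$neural_effect))
  z_risk <- matrix(NA_real_, n, length(RISK_ROIS),
                   dimnames = list(NULL, RISK_ROIS))
  for (i in seq_len(n)) {
    val_true <- valuate_sequence(task, model_params(l_true[i],
                                                    config$params$payoff_scale))
    val_hat <- valuate_sequence(task, model_params(l_hat[i],
                                                   config$params$payoff_scale))
    design_hat <- build_design(val_hat, subjects[[i]]$dataset$choices,
                               config$layout)
    for (r in seq_along(RISK_ROIS)) {
      sim <- simulate_task_bold(val_true, subjects[[i]]$dataset$choices,
                                betas = c(risk = unname(beta_risk[i, r]),
                                          reward = 1, entropy = 1),
                                layout = config$layout,
                                noise_sd = ccfg$bold_noise_sd,
                                ar1 = ccfg$bold_ar1,
                                seed = seed + 4000L + i * 10L + r)
      z_risk[i, r] <- fit_glm(sim$series, design_hat)$z[["risk"]]
    }
  }
  stamp("glm")

  # --- resting state + rsFC -------------------------------------------
  set.seed(seed + 5L)
  z_pi_str <- atanh(config$rsfc_base) +
    config$rsfc_z_sd * .corr_draw(zns, ccfg$rsfc_effect)
  z_pi_ai <- atanh(config$rsfc_base) +
    config$rsfc_z_sd * .corr_draw(zns, ccfg$rsfc_effect)
  clamp <- atanh(0.7)
  z_pi_str <- pmin(pmax(z_pi_str, -clamp), clamp)
  z_pi_ai <- pmin(pmax(z_pi_ai, -clamp), clamp)
  n_spikes <- stats::rpois(n, 2)
  fc <- vector("list", n)
  for (i in seq_len(n)) {
    R <- .rest_target_matrix(config$rsfc_base, z_pi_str[i], z_pi_ai[i])
    sv <- if (n_spikes[i] > 0) sort(sample(2:240, n_spikes[i])) else integer(0)
    rest <- simulate_resting_state(R, spike_volumes = sv,
                                   noise_sd = ccfg$rest_noise_sd,
                                   seed = seed + 6000L + i)
    fc[[i]] <- rsfc_pipeline(rest$series, rest$motion)$pairs
  }
  pair_names <- paste(fc[[1]]$roi_a, fc[[1]]$roi_b, sep = "-")
  z_fc <- t(vapply(fc, function(p) p$z, numeric(nrow(fc[[1]]))))
  colnames(z_fc) <- pair_names
  stamp("rsfc")

  # --- group statistics ------------------------------------------------
  cor_ns_l <- pearson(ns, l_hat, config$alpha, 1L)
  activation <- lapply(RISK_ROIS, function(r)
    list(roi = r,
         correlation = pearson(ns, z_risk[, r], config$alpha,
                               length(RISK_ROIS)),
         group_test = group_activation_test(z_risk[, r])))
  names(activation) <- RISK_ROIS
  partial <- lapply(RISK_ROIS, function(r)
    partial_correlation(ns, z_risk[, r], l_hat, config$alpha,
                        length(RISK_ROIS)))
  names(partial) <- RISK_ROIS
  rsfc_cor <- lapply(pair_names, function(p)
    pearson(ns, z_fc[, p], config$alpha, length(pair_names)))
  names(rsfc_cor) <- pair_names
  mediation <- sobel_mediation(z_risk[, config$mediation_roi], l_hat, ns)
  stamp("stats")

  report <- list(
    subjects = data.frame(subject_id = vapply(subjects, `[[`, character(1),
                                              "subject_id"),
                          ns_score = ns, l_true = l_true, l_hat = l_hat,
                          mll = vapply(fits, `[[`, numeric(1), "mll"),
                          accuracy = vapply(fits, `[[`, numeric(1),
                                            "accuracy"),
                          z_risk, z_fc, check.names = FALSE),
    fits = fits, table1 = table1, cor_ns_l = cor_ns_l,
    activation = activation, partial = partial, rsfc = rsfc_cor,
    mediation = mediation,
    achieved_rho_ns_l = attr(subjects, "achieved_rho_ns_l"),
    config = config, log = log)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}
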