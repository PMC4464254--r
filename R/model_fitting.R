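# Maximum-likelihood estimation of the risk-preference weight and the
# goodness-of-fit statistics used to compare model and random agents.

#' Search configuration for the risk-preference MLE
#'
#' The optimizer evaluates the log-likelihood on an even grid over the
#' parameter bounds and then runs seeded golden-section refinements inside
#' randomly chosen high-likelihood grid neighbourhoods.
#'
#' @param n_grid_steps number of grid points over the bounds (default 1000).
#' @param n_restarts number of local refinements (default 4).
#' @param bounds parameter bounds for `l` (default c(-1, 1)).
#' @param seed integer seed making the restart draw deterministic.
#' @return An object of class `search_config`.
#' @export
search_config <- function(n_grid_steps = 1000L, n_restarts = 4L,
                          bounds = c(-1, 1), seed = 1L) {
  if (n_grid_steps < 2L) stop("n_grid_steps must be >= 2")
  if (length(bounds) != 2L || bounds[1] >= bounds[2])
    stop("bounds must be an ordered pair")
  structure(list(n_grid_steps = as.integer(n_grid_steps),
                 n_restarts = as.integer(n_restarts),
                 bounds = as.numeric(bounds), seed = seed),
            class = "search_config")
}

# Precompute the pieces of the likelihood that do not depend on l:
# per-trial, per-deck expected reward E and risk V, and the chosen columns.
.ll_prep <- function(dataset, params) {
  val <- valuate_sequence(dataset$task, model_params(0, params$payoff_scale,
                                                     params$risk_as_sd))
  n <- dataset$task$n_trials
  idx <- cbind(seq_len(n), dataset$choices)
  list(E = val$expected_reward, V = val$risk,
       Ec = val$expected_reward[idx], Vc = val$risk[idx], n = n)
}

# Summed log-likelihood at a single l, from a .ll_prep object.
.ll_at <- function(prep, l) {
  U <- prep$E + l * prep$V
  m <- pmax(U[, 1L], U[, 2L], U[, 3L], U[, 4L])
  lse <- m + log(exp(U[, 1L] - m) + exp(U[, 2L] - m) +
                 exp(U[, 3L] - m) + exp(U[, 4L] - m))
  sum(prep$Ec + l * prep$Vc - lse)
}

# Summed log-likelihood over a whole grid of l values at once.
.ll_grid <- function(prep, lgrid) {
  U1 <- prep$E[, 1L] + outer(prep$V[, 1L], lgrid)
  U2 <- prep$E[, 2L] + outer(prep$V[, 2L], lgrid)
  U3 <- prep$E[, 3L] + outer(prep$V[, 3L], lgrid)
  U4 <- prep$E[, 4L] + outer(prep$V[, 4L], lgrid)
  m <- pmax(U1, U2, U3, U4)
  lse <- m + log(exp(U1 - m) + exp(U2 - m) + exp(U3 - m) + exp(U4 - m))
  Uc <- prep$Ec + outer(prep$Vc, lgrid)
  colSums(Uc - lse)
}

#' Summed log-likelihood of a choice dataset
#'
#' @param dataset a `choice_dataset`.
#' @param l risk-preference weight.
#' @param params model parameters (the `risk_preference` field is ignored;
#'   `l` is used).
#' @return the summed log-likelihood (<= 0).
#' @export
log_likelihood <- function(dataset, l, params = model_params()) {
  if (is.null(dataset$choices) || anyNA(dataset$choices))
    stop("every trial must have a recorded choice")
  .ll_at(.ll_prep(dataset, params), l)
}

#' Fit the risk-preference weight by maximum likelihood
#'
#' Maximizes the summed log-likelihood of the observed choices over
#' `l` in the search bounds, using an even grid plus seeded golden-section
#' refinements ([search_config()]). Exact likelihood ties are broken toward
#' the smallest absolute `l`.
#'
#' @param dataset a `choice_dataset`.
#' @param search a `search_config`.
#' @param params model parameters (payoff scale, risk form).
#' @return An object of class `fit_result` with fields `l_hat`, `ll`
#'   (summed log-likelihood), `mll` (per-trial mean negative log-likelihood,
#'   nats/trial), `accuracy` (argmax prediction accuracy), `n_trials`,
#'   `k_params` (= 1) and, once a dataset-group size is supplied to
#'   [information_criteria()], `aic`, `aicc`, `bic`.
#' @export
fit_risk_preference <- function(dataset, search = search_config(),
                                params = model_params()) {
  if (is.null(dataset$choices) || length(dataset$choices) == 0L)
    stop("dataset is empty: nothing to fit")
  prep <- .ll_prep(dataset, params)
  lgrid <- seq(search$bounds[1], search$bounds[2],
               length.out = search$n_grid_steps)
  llg <- .ll_grid(prep, lgrid)
  step <- lgrid[2L] - lgrid[1L]
  best <- which.max(llg)

  # seeded restarts: golden-section refinement inside the best grid
  # neighbourhood plus randomly drawn neighbourhoods among the top points
  top <- order(llg, decreasing = TRUE)[seq_len(min(25L, length(lgrid)))]
  starts <- best
  if (search$n_restarts > 0L) {
    if (!is.null(search$seed)) set.seed(search$seed)
    starts <- unique(c(best, top[sample.int(length(top),
                                            min(search$n_restarts, length(top)))]))
  }
  cand_l <- lgrid[starts]
  cand_ll <- llg[starts]
  for (s in starts) {
    lo <- max(search$bounds[1], lgrid[s] - step)
    hi <- min(search$bounds[2], lgrid[s] + step)
    op <- stats::optimize(function(l) .ll_at(prep, l), lower = lo, upper = hi,
                          maximum = TRUE, tol = 1e-9)
    cand_l <- c(cand_l, op$maximum)
    cand_ll <- c(cand_ll, op$objective)
  }
  # best candidate; ties toward smallest |l|
  ok <- cand_ll >= max(cand_ll) - 1e-12
  l_hat <- cand_l[ok][which.min(abs(cand_l[ok]))]
  ll <- .ll_at(prep, l_hat)

  structure(list(l_hat = l_hat, ll = ll, mll = -ll / prep$n,
                 accuracy = prediction_accuracy(dataset, l_hat, params),
                 n_trials = prep$n, k_params = 1L,
                 aic = NA_real_, aicc = NA_real_, bic = NA_real_),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Risk-preference fit: l_hat = %.4f, MLL = %.4f nats/trial, accuracy = %.1f%% (%d trials)\n",
              x$l_hat, x$mll, 100 * x$accuracy, x$n_trials))
  invisible(x)
}

#' Argmax prediction accuracy of the fitted model
#'
#' The deck with maximal model probability is the predicted choice;
#' probability ties are broken toward the lowest deck index (A first).
#'
#' @param dataset a `choice_dataset`.
#' @param l_hat fitted risk preference.
#' @param params model parameters.
#' @return fraction of trials where the predicted deck equals the chosen one.
#' @export
prediction_accuracy <- function(dataset, l_hat, params = model_params()) {
  val <- valuate_sequence(dataset$task,
                          model_params(l_hat, params$payoff_scale,
                                       params$risk_as_sd))
  pred <- apply(val$probabilities, 1L, which.max)  # first max = lowest index
  mean(pred == dataset$choices)
}

#' Information criteria under the per-trial / group-size convention
#'
#' With `mll` the per-trial mean negative log-likelihood and `k` the number
#' of free parameters, AIC = 2k + 2*mll and AICc adds the usual small-sample
#' correction 2k(k+1)/(M-k-1); BIC = k*log(M) + 2*mll. The sample-size term
#' `M` is the number of datasets in the comparison group (e.g. 1000 random
#' agents), not the number of trials — an unusual convention, documented in
#' the methods vignette, chosen because it is the one the reference group
#' statistics follow.
#'
#' @param mll per-trial mean negative log-likelihood (nats/trial), >= 0.
#' @param k number of free parameters (default 1: the risk preference).
#' @param M dataset-group size; must exceed k + 1.
#' @return named numeric vector `c(aic, aicc, bic)`.
#' @export
information_criteria <- function(mll, k = 1L, M) {
  if (any(mll < 0)) stop("mll must be non-negative")
  if (k < 1L) stop("k must be >= 1")
  if (M <= k + 1L) stop("group size M must exceed k + 1")
  aic <- 2 * k + 2 * mll
  c(aic = aic, aicc = aic + 2 * k * (k + 1) / (M - k - 1), bic = k * log(M) + 2 * mll)
}

# per-fit statistic table for a group of fits, with ICs at group size M
.fit_stats <- function(fits, M = length(fits)) {
  mll <- vapply(fits, `[[`, numeric(1), "mll")
  k <- vapply(fits, `[[`, numeric(1), "k_params")
  ic <- t(vapply(mll, information_criteria, numeric(3), k = k[1L], M = M))
  data.frame(mll = mll, aic = ic[, "aic"], aicc = ic[, "aicc"],
             bic = ic[, "bic"])
}

#' Compare goodness-of-fit statistics between two groups of fits
#'
#' Classic pooled-variance independent-samples t-test per statistic (MLL,
#' AIC, AICc, BIC), with each group's information criteria computed at its
#' own group size.
#'
#' @param fits_a,fits_b lists of `fit_result` objects (each of length >= 2).
#' @param M_a,M_b group sizes used for the information criteria (default the
#'   number of fits supplied; override when the fits are a subsample of a
#'   nominally larger group).
#' @return A data.frame with one row per statistic: group means and SDs,
#'   pooled t, degrees of freedom and two-tailed p.
#' @export
compare_fit_groups <- function(fits_a, fits_b, M_a = length(fits_a),
                               M_b = length(fits_b)) {
  if (length(fits_a) < 2L || length(fits_b) < 2L)
    stop("each group must contain at least 2 fits")
  sa <- .fit_stats(fits_a, M_a)
  sb <- .fit_stats(fits_b, M_b)
  out <- lapply(names(sa), function(st) {
    tt <- stats::t.test(sa[[st]], sb[[st]], var.equal = TRUE)
    data.frame(statistic = st,
               mean_a = mean(sa[[st]]), sd_a = stats::sd(sa[[st]]),
               mean_b = mean(sb[[st]]), sd_b = stats::sd(sb[[st]]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
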