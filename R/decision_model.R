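# Mean-variance utility model with softmax choice and entropy-based
# choice difficulty.
#
# For a deck showing value x with scaled payoffs W (win) and L (loss
# magnitude) and win probability p = win_probability(x):
#   reward prediction  r_hat = p*W - (1-p)*L
#   risk prediction    Risk  = p*(1-p)*(W+L)^2   (two-outcome variance)
#   utility            U     = r_hat + l * Risk
# and choice probabilities follow a softmax over the four utilities.

#' Model parameters for the mean-variance utility model
#'
#' @param risk_preference risk-preference weight `l` in \[-1, 1\]; negative
#'   values are risk-averse, positive risk-seeking.
#' @param payoff_scale positive divisor applied to point payoffs before
#'   valuation so utilities are O(1) (the softmax has no temperature
#'   parameter). The default 125 is the largest payoff magnitude; the
#'   methods vignette reports the sensitivity of the goodness-of-fit
#'   statistics and of parameter recovery to this choice.
#' @param risk_as_sd if TRUE, risk enters the utility as the standard
#'   deviation rather than the variance (off by default; the model's risk
#'   term is the variance).
#' @return An object of class `model_params`.
#' @export
model_params <- function(risk_preference = 0, payoff_scale = 125,
                         risk_as_sd = FALSE) {
  if (length(risk_preference) != 1L || is.na(risk_preference) ||
      risk_preference < -1 || risk_preference > 1)
    stop("risk_preference must be a single value in [-1, 1]")
  if (length(payoff_scale) != 1L || is.na(payoff_scale) || payoff_scale <= 0)
    stop("payoff_scale must be a positive number")
  structure(list(risk_preference = risk_preference,
                 payoff_scale = payoff_scale,
                 risk_as_sd = isTRUE(risk_as_sd)),
            class = "model_params")
}

#' Expected reward of a deck
#'
#' @param p win probability in \[0, 1\].
#' @param W scaled winning payoff.
#' @param L scaled losing payoff (positive magnitude).
#' @return p*W - (1-p)*L, vectorized.
#' @export
reward_prediction <- function(p, W, L) {
  if (any(p < 0 | p > 1 | is.na(p)))
    stop("win probability p must lie in [0, 1]")
  p * W - (1 - p) * L
}

#' Risk prediction (payoff variance) of a deck
#'
#' The expected squared reward-prediction error of the two-outcome gamble:
#' p*(1-p)*(W+L)^2.
#'
#' @inheritParams reward_prediction
#' @return the two-outcome variance, vectorized; always >= 0.
#' @export
risk_prediction <- function(p, W, L) {
  if (any(p < 0 | p > 1 | is.na(p)))
    stop("win probability p must lie in [0, 1]")
  p * (1 - p) * (W + L)^2
}

#' Mean-variance utility
#'
#' @param expected_reward reward prediction.
#' @param risk risk prediction (variance), >= 0.
#' @param l risk-preference weight.
#' @return expected_reward + l * risk.
#' @export
utility <- function(expected_reward, risk, l) {
  if (any(risk < 0)) stop("risk must be non-negative")
  expected_reward + l * risk
}

#' Softmax choice probabilities
#'
#' Overflow-safe softmax (max-subtraction). Accepts a vector of utilities or
#' a matrix with one row per trial.
#'
#' @param utilities numeric vector or matrix of finite utilities.
#' @return probabilities of the same shape, each row summing to 1.
#' @export
choice_probabilities <- function(utilities) {
  if (!all(is.finite(utilities))) stop("utilities must be finite")
  if (is.matrix(utilities)) {
    m <- utilities - apply(utilities, 1L, max)
    e <- exp(m)
    e / rowSums(e)
  } else {
    e <- exp(utilities - max(utilities))
    e / sum(e)
  }
}

#' Shannon entropy of a choice-probability vector
#'
#' Measures the difficulty of the choice comparison in nats:
#' H = -sum(P * log(P)), with 0*log(0) = 0. Maximal (log 4) when all four
#' decks are equally attractive.
#'
#' @param probabilities numeric vector of probabilities summing to 1 (or a
#'   matrix with one row per trial).
#' @return entropy in nats.
#' @export
trial_entropy <- function(probabilities) {
  if (any(probabilities < 0)) stop("probabilities must be non-negative")
  if (is.matrix(probabilities)) {
    s <- rowSums(probabilities)
    if (any(abs(s - 1) > 1e-8)) stop("each row of probabilities must sum to 1")
    pl <- probabilities * log(probabilities)
    pl[probabilities == 0] <- 0
    -rowSums(pl)
  } else {
    if (abs(sum(probabilities) - 1) > 1e-8) stop("probabilities must sum to 1")
    pl <- probabilities * log(probabilities)
    pl[probabilities == 0] <- 0
    -sum(pl)
  }
}

# scaled win/loss vectors for the four decks
.scaled_payoffs <- function(specs, payoff_scale) {
  list(W = specs$win / payoff_scale, L = specs$loss / payoff_scale)
}

#' Valuate a single trial
#'
#' Computes, for the four displayed values of one trial: per-deck win
#' probability, expected reward, risk prediction, utility, softmax choice
#' probabilities, and the trial's choice-difficulty entropy.
#'
#' @param shown_values the four displayed card values (deck order A-D).
#' @param specs deck payoff schedule.
#' @param params model parameters ([model_params()]).
#' @return A list with `p`, `expected_reward`, `risk`, `utility`,
#'   `probabilities` (each length 4, named A-D) and `entropy`.
#' @export
valuate_trial <- function(shown_values, specs = deck_specs(),
                          params = model_params()) {
  sv <- as.integer(unlist(shown_values))
  if (length(sv) != 4L) stop("shown_values must give one value per deck")
  pay <- .scaled_payoffs(specs, params$payoff_scale)
  p <- win_probability(sv)
  ev <- reward_prediction(p, pay$W, pay$L)
  rk <- risk_prediction(p, pay$W, pay$L)
  if (params$risk_as_sd) rk <- sqrt(rk)
  u <- utility(ev, rk, params$risk_preference)
  pr <- choice_probabilities(u)
  names(p) <- names(ev) <- names(rk) <- names(u) <- names(pr) <- DECK_NAMES
  list(p = p, expected_reward = ev, risk = rk, utility = u,
       probabilities = pr, entropy = trial_entropy(pr))
}

#' Valuate every trial of a task sequence
#'
#' Matrix form of [valuate_trial()], used by the fitting and regressor
#' construction stages.
#'
#' @param task a `task_sequence`.
#' @param params model parameters.
#' @return An object of class `trial_valuations`: a list of n x 4 matrices
#'   `p`, `expected_reward`, `risk`, `utility`, `probabilities` and the
#'   length-n vector `entropy`.
#' @export
valuate_sequence <- function(task, params = model_params()) {
  pay <- .scaled_payoffs(task$deck_specs, params$payoff_scale)
  n <- task$n_trials
  p <- matrix(win_probability(as.vector(task$values)), n, 4L,
              dimnames = list(NULL, DECK_NAMES))
  Wm <- matrix(pay$W, n, 4L, byrow = TRUE)
  Lm <- matrix(pay$L, n, 4L, byrow = TRUE)
  ev <- p * Wm - (1 - p) * Lm
  rk <- p * (1 - p) * (Wm + Lm)^2
  if (params$risk_as_sd) rk <- sqrt(rk)
  u <- ev + params$risk_preference * rk
  pr <- choice_probabilities(u)
  structure(list(p = p, expected_reward = ev, risk = rk, utility = u,
                 probabilities = pr, entropy = trial_entropy(pr),
                 params = params),
            class = "trial_valuations")
}

#' Tidy per-trial, per-deck valuation table
#'
#' @param x a `trial_valuations` object.
#' @param ... unused.
#' @return A data.frame with one row per trial x deck: `trial`, `deck`,
#'   `p_win`, `expected_reward`, `risk`, `utility`, `probability`, `entropy`.
#' @export
as.data.frame.trial_valuations <- function(x, ...) {
  n <- nrow(x$p)
  data.frame(trial = rep(seq_len(n), 4L),
             deck = rep(DECK_NAMES, each = n),
             p_win = as.vector(x$p),
             expected_reward = as.vector(x$expected_reward),
             risk = as.vector(x$risk),
             utility = as.vector(x$utility),
             probability = as.vector(x$probabilities),
             entropy = rep(x$entropy, 4L),
             stringsAsFactors = FALSE)
}
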