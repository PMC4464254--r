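# Four-deck probabilistic card task: stimulus generation, payoff schedule,
# and outcome realization.

# Card-value universe: the arithmetic sequence 0, 5, ..., 100.
CARD_VALUES <- seq(0L, 100L, by = 5L)
DECK_NAMES <- c("A", "B", "C", "D")

#' Deck payoff schedule
#'
#' Defines the win/loss point amounts for the four decks. By default the
#' high-stakes decks A and B win 100 points or lose 125 points; the
#' low-stakes decks C and D win 50 points or lose 25 points. Loss amounts
#' are positive magnitudes.
#'
#' @param win named numeric vector of winning points per deck (A, B, C, D).
#' @param loss named numeric vector of losing point magnitudes per deck.
#' @return A data.frame with columns `deck`, `win`, `loss`.
#' @examples
#' deck_specs()
#' @export
deck_specs <- function(win = c(A = 100, B = 100, C = 50, D = 50),
                       loss = c(A = 125, B = 125, C = 25, D = 25)) {
  win <- win[DECK_NAMES]
  loss <- loss[DECK_NAMES]
  if (anyNA(win) || anyNA(loss))
    stop("deck payoffs must be named for all four decks A, B, C, D")
  if (any(win <= 0) || any(loss <= 0))
    stop("win and loss amounts must be positive magnitudes")
  data.frame(deck = DECK_NAMES, win = unname(win), loss = unname(loss),
             stringsAsFactors = FALSE)
}

# uniform draw from a set, avoiding sample()'s length-1 surprise
.draw1 <- function(pool) pool[sample.int(length(pool), 1L)]

#' Generate a task stimulus sequence
#'
#' Draws the four displayed card values for each trial, uniformly over the
#' values admissible under the task constraints: values come from
#' {0, 5, ..., 100}; within a trial deck A's value differs from deck B's and
#' deck C's from deck D's (those pairs share a payoff schedule); and within
#' each deck the value differs from that deck's value on the previous trial.
#'
#' @param n_trials number of trials (default 180).
#' @param specs deck payoff schedule from [deck_specs()].
#' @param seed integer seed; the same seed always yields the same sequence.
#' @return An object of class `task_sequence`: a list with `values` (an
#'   `n_trials` x 4 integer matrix with columns A-D), `deck_specs`,
#'   `n_trials` and `seed`.
#' @examples
#' task <- generate_task_sequence(10, seed = 1)
#' task$values
#' @export
generate_task_sequence <- function(n_trials = 180L, specs = deck_specs(),
                                   seed = NULL) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    stop("n_trials must be a single integer >= 1")
  n_trials <- as.integer(n_trials)
  if (!is.null(seed)) set.seed(seed)

  v <- matrix(0L, n_trials, 4L, dimnames = list(NULL, DECK_NAMES))
  prev <- rep(NA_integer_, 4L)
  for (t in seq_len(n_trials)) {
    a <- .draw1(setdiff(CARD_VALUES, prev[1L]))
    b <- .draw1(setdiff(CARD_VALUES, c(prev[2L], a)))
    cc <- .draw1(setdiff(CARD_VALUES, prev[3L]))
    d <- .draw1(setdiff(CARD_VALUES, c(prev[4L], cc)))
    v[t, ] <- c(a, b, cc, d)
    prev <- v[t, ]
  }
  structure(list(values = v, deck_specs = specs, n_trials = n_trials,
                 seed = seed),
            class = "task_sequence")
}

#' @export
print.task_sequence <- function(x, ...) {
  cat("Four-deck task sequence:", x$n_trials, "trials\n")
  cat("Payoffs: A/B +", x$deck_specs$win[1], "/-", x$deck_specs$loss[1],
      "; C/D +", x$deck_specs$win[3], "/-", x$deck_specs$loss[3], "\n", sep = "")
  print(utils::head(x$values, 5))
  if (x$n_trials > 5) cat("... (", x$n_trials - 5, " more trials)\n", sep = "")
  invisible(x)
}

#' Probability that a shown card value wins
#'
#' The hidden second card is uniform over the 20 universe values different
#' from the shown value, and the trial is won iff the shown value is strictly
#' greater. Hence the win probability is the count of universe values below
#' the shown value, divided by 20.
#'
#' @param card_value card value(s) in {0, 5, ..., 100}.
#' @return win probability in [0, 1], vectorized over `card_value`.
#' @examples
#' win_probability(c(0, 50, 100))
#' @export
win_probability <- function(card_value) {
  if (!all(card_value %in% CARD_VALUES))
    stop("card_value must lie in the universe {0, 5, ..., 100}")
  vapply(card_value, function(v) sum(CARD_VALUES < v) / 20, numeric(1))
}

# vectorized second-card draw: uniform over the 20 universe values != first
.draw_second <- function(first) {
  r <- first %/% 5L + 1L                 # rank of first card in 1..21
  j <- sample.int(20L, length(first), replace = TRUE)
  CARD_VALUES[ifelse(j >= r, j + 1L, j)]
}

#' Realize the outcome of one trial
#'
#' Draws the hidden second card (uniform over the 20 values different from
#' the shown value) and applies the payoff rule: win `win` points if the
#' shown value beats the second card, otherwise lose `loss` points. Ties are
#' impossible by construction.
#'
#' @param shown_values the four displayed values for the trial (named A-D or
#'   in deck order).
#' @param chosen_deck one of "A","B","C","D".
#' @param specs deck payoff schedule.
#' @return A one-row data.frame: `choice`, `first_card`, `second_card`,
#'   `won`, `delta`.
#' @export
realize_outcome <- function(shown_values, chosen_deck, specs = deck_specs()) {
  k <- match(chosen_deck, DECK_NAMES)
  if (is.na(k)) stop("chosen_deck must be one of A, B, C, D")
  first <- as.integer(shown_values[[k]])
  second <- .draw_second(first)
  won <- first > second
  delta <- if (won) specs$win[k] else -specs$loss[k]
  data.frame(choice = chosen_deck, first_card = first, second_card = second,
             won = won, delta = delta, stringsAsFactors = FALSE)
}

#' Realize outcomes for a whole choice sequence
#'
#' @param task a `task_sequence`.
#' @param choices integer vector (1-4) or letter vector of chosen decks,
#'   one per trial.
#' @return A data.frame with one row per trial: `trial`, `choice`,
#'   `first_card`, `second_card`, `won`, `delta`.
#' @export
realize_outcomes <- function(task, choices) {
  ch <- if (is.character(choices)) match(choices, DECK_NAMES) else as.integer(choices)
  if (length(ch) != task$n_trials || anyNA(ch) || any(ch < 1L | ch > 4L))
    stop("choices must give a valid deck for every trial")
  first <- task$values[cbind(seq_len(task$n_trials), ch)]
  second <- .draw_second(first)
  won <- first > second
  specs <- task$deck_specs
  delta <- ifelse(won, specs$win[ch], -specs$loss[ch])
  data.frame(trial = seq_len(task$n_trials), choice = DECK_NAMES[ch],
             first_card = first, second_card = second, won = won,
             delta = delta, stringsAsFactors = FALSE)
}

#' Total score of a set of realized outcomes
#'
#' @param outcomes a data.frame with a `delta` column (or a numeric vector of
#'   per-trial point deltas).
#' @return the summed signed points.
#' @export
total_score <- function(outcomes) {
  delta <- if (is.data.frame(outcomes)) outcomes$delta else outcomes
  if (length(delta) == 0L) return(0)
  sum(delta)
}

#' Bundle a task, choices and outcomes into a choice dataset
#'
#' @param task a `task_sequence`.
#' @param choices integer (1-4) choices per trial.
#' @param outcomes optional realized outcomes (from [realize_outcomes()]);
#'   realized on the spot if missing.
#' @return An object of class `choice_dataset`.
#' @export
choice_dataset <- function(task, choices, outcomes = NULL) {
  ch <- if (is.character(choices)) match(choices, DECK_NAMES) else as.integer(choices)
  if (length(ch) != task$n_trials || anyNA(ch) || any(ch < 1L | ch > 4L))
    stop("choices must give a valid deck for every trial")
  if (is.null(outcomes)) outcomes <- realize_outcomes(task, ch)
  structure(list(task = task, choices = ch, outcomes = outcomes),
            class = "choice_dataset")
}

#' @export
print.choice_dataset <- function(x, ...) {
  cat("Choice dataset:", x$task$n_trials, "trials, total score",
      total_score(x$outcomes), "\n")
  tb <- table(factor(DECK_NAMES[x$choices], levels = DECK_NAMES))
  cat("Deck counts:", paste(DECK_NAMES, as.integer(tb), sep = "=", collapse = " "), "\n")
  invisible(x)
}
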