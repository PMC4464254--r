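# Small fixtures shared across test files. Everything is generated in code.

tiny_task <- function(n = 10, seed = 7) generate_task_sequence(n, seed = seed)

# a fixed 3-trial task with hand-chosen card values, for worked examples
fixed_task <- function(values) {
  v <- matrix(as.integer(values), ncol = 4, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  structure(list(values = v, deck_specs = deck_specs(), n_trials = nrow(v),
                 seed = NULL),
            class = "task_sequence")
}

# independent softmax oracle, written differently from the package path
oracle_softmax <- function(u) exp(u) / sum(exp(u))

# independent per-trial choice probability oracle for the utility model
oracle_trial_probs <- function(values, l, scale = 125) {
  win <- c(100, 100, 50, 50) / scale
  loss <- c(125, 125, 25, 25) / scale
  p <- sapply(values, function(v) sum(seq(0, 100, 5) < v) / 20)
  ev <- p * win - (1 - p) * loss
  vr <- p * (1 - p) * (win + loss)^2
  oracle_softmax(ev + l * vr)
}
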