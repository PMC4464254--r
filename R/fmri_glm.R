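# Parametric-modulation GLM on ROI time series: block layout, gamma HRF,
# design construction, OLS fit with z-transformed effects, group test.

#' Gamma haemodynamic response kernel
#'
#' Single-gamma HRF h(t) = (t/(p*q))^p * exp(p - t/q) for t > 0, which has
#' unit peak at t = p*q (about 4.7 s with the defaults) and has decayed to
#' under 1% of peak by 25 s.
#'
#' @param t time grid in seconds (values <= 0 give 0).
#' @param p shape exponent (default 8.6).
#' @param q time scale in seconds (default 0.547).
#' @return kernel values on `t`.
#' @export
gamma_hrf <- function(t, p = 8.6, q = 0.547) {
  if (p <= 0 || q <= 0) stop("HRF shape parameters must be positive")
  h <- numeric(length(t))
  pos <- t > 0
  h[pos] <- (t[pos] / (p * q))^p * exp(p - t[pos] / q)
  h
}

#' Block layout of the scanning session
#'
#' Each run starts with a rest (fixation) block and then alternates task
#' blocks of `trials_per_block` back-to-back trials with rest blocks:
#' rest + (task + rest) x blocks_per_run. With the defaults (30 s rest,
#' 20 trials x 5 s task blocks, 3 blocks, 3 runs) each run lasts 420 s
#' (7 min, 210 volumes at TR 2 s) and the session holds 180 trials.
#'
#' @param n_runs,blocks_per_run,trials_per_block session structure.
#' @param trial_dur trial duration in seconds (4 s choice + 1 s outcome).
#' @param rest_dur rest-block duration in seconds.
#' @param TR repetition time in seconds.
#' @return A list with trial `onsets` (s, session clock), `run` per trial,
#'   `run_dur`, `n_volumes` per run, `vol_times`, `vol_run`, and the layout
#'   parameters.
#' @export
block_layout <- function(n_runs = 3L, blocks_per_run = 3L,
                         trials_per_block = 20L, trial_dur = 5,
                         rest_dur = 30, TR = 2) {
  run_dur <- rest_dur + blocks_per_run * (trials_per_block * trial_dur + rest_dur)
  nv <- run_dur / TR
  if (abs(nv - round(nv)) > 1e-9) stop("run duration must be a multiple of TR")
  nv <- as.integer(round(nv))
  onsets <- numeric(0); run <- integer(0)
  for (r in seq_len(n_runs)) {
    t0 <- (r - 1) * run_dur
    for (b in seq_len(blocks_per_run)) {
      bstart <- t0 + rest_dur + (b - 1) * (trials_per_block * trial_dur + rest_dur)
      onsets <- c(onsets, bstart + trial_dur * (seq_len(trials_per_block) - 1))
      run <- c(run, rep(r, trials_per_block))
    }
  }
  vol_times <- TR * (seq_len(n_runs * nv) - 1)
  list(onsets = onsets, run = run, run_dur = run_dur, n_volumes = nv,
       n_runs = n_runs, vol_times = vol_times,
       vol_run = rep(seq_len(n_runs), each = nv), TR = TR,
       trial_dur = trial_dur, rest_dur = rest_dur)
}

# Convolve per-run modulated impulse trains with the HRF and sample at TR.
# onsets/amplitudes are within-run (run clock starting at 0).
.convolve_regressor <- function(onsets, amplitudes, run_dur, TR, hrf_fun,
                                dt = 0.1) {
  ng <- as.integer(round(run_dur / dt))
  x <- numeric(ng)
  idx <- as.integer(round(onsets / dt)) + 1L
  if (any(idx < 1L | idx > ng)) stop("trial onsets fall outside the run")
  x[idx] <- x[idx] + amplitudes
  h <- hrf_fun(seq(0, 32, by = dt))
  y <- stats::convolve(x, rev(h), type = "open")[seq_len(ng)]
  y[as.integer(round(seq(0, run_dur - TR, by = TR) / dt)) + 1L]
}

#' Build a parametric-modulation design matrix
#'
#' Constructs per-run baseline columns plus regressors for the trial-by-trial
#' risk prediction, reward prediction and choice-difficulty entropy of the
#' chosen model: each modulator scales an impulse at its trial onset
#' (mean-centered within run when `mean_center` is TRUE, decoupling the
#' parametric effect from the baseline), and the impulse train is convolved
#' with the gamma HRF and sampled on the TR grid. Rest blocks contribute
#' zeros. Six motion columns may be appended.
#'
#' @param valuations a `trial_valuations` object covering all trials.
#' @param choices integer chosen deck per trial (1-4); the risk and reward
#'   modulators are the chosen deck's predictions.
#' @param layout a [block_layout()].
#' @param hrf_fun HRF kernel function of time (default [gamma_hrf()]).
#' @param mean_center mean-center modulators within run (default TRUE).
#' @param motion optional volumes x 6 motion table appended as nuisance
#'   columns.
#' @return An object of class `fmri_design`: list with matrix `X`, `layout`,
#'   and the condition number `kappa`.
#' @export
build_design <- function(valuations, choices, layout = block_layout(),
                         hrf_fun = gamma_hrf, mean_center = TRUE,
                         motion = NULL) {
  n_tr <- length(layout$onsets)
  if (nrow(valuations$risk) != n_tr)
    stop("valuations must cover exactly the trials in the layout")
  idx <- cbind(seq_len(n_tr), choices)
  mods <- list(risk = valuations$risk[idx],
               reward = valuations$expected_reward[idx],
               entropy = valuations$entropy)
  nv <- layout$n_volumes
  X_par <- matrix(0, layout$n_runs * nv, 3L,
                  dimnames = list(NULL, names(mods)))
  for (r in seq_len(layout$n_runs)) {
    in_run <- layout$run == r
    on_r <- layout$onsets[in_run] - (r - 1) * layout$run_dur
    rows <- ((r - 1) * nv + 1L):(r * nv)
    for (j in seq_along(mods)) {
      a <- mods[[j]][in_run]
      if (mean_center) a <- a - mean(a)
      X_par[rows, j] <- .convolve_regressor(on_r, a, layout$run_dur,
                                            layout$TR, hrf_fun)
    }
  }
  base <- stats::model.matrix(~ 0 + factor(layout$vol_run))
  colnames(base) <- paste0("run", seq_len(layout$n_runs))
  X <- cbind(base, X_par)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nrow(X) || ncol(motion) != 6L)
      stop("motion must be a volumes x 6 table")
    colnames(motion) <- paste0("motion", 1:6)
    X <- cbind(X, motion)
  }
  # a degenerate (all-zero) parametric column, e.g. a centered constant
  # modulator, is left in place; fit_glm reports it as rank deficiency
  structure(list(X = X, layout = layout, kappa = kappa(X, exact = TRUE),
                 zero_columns = colnames(X)[apply(X, 2L, function(cl)
                   all(cl == 0))]),
            class = "fmri_design")
}

#' Fit the GLM to one ROI time series
#'
#' Ordinary least squares with standard errors from the residual variance;
#' the z-transformed effect is beta/SE.
#'
#' @param series numeric BOLD vector, one value per volume.
#' @param design an `fmri_design` (or a plain design matrix).
#' @return An object of class `glm_result`: `beta`, `se`, `z`, `sigma2`,
#'   `df`, `residuals`.
#' @export
fit_glm <- function(series, design) {
  X <- if (inherits(design, "fmri_design")) design$X else as.matrix(design)
  if (length(series) != nrow(X))
    stop("series length must equal the number of design rows")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, series)
  res <- series - as.vector(X %*% beta)
  df <- length(series) - ncol(X)
  if (df <= 0) stop("no residual degrees of freedom")
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(chol2inv(qr.R(qx))))[order(qx$pivot)]
  names(se) <- names(beta)
  structure(list(beta = beta, se = se, z = beta / se, sigma2 = sigma2,
                 df = df, residuals = res),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat("ROI GLM fit (df =", x$df, ")\n")
  print(round(data.frame(beta = x$beta, se = x$se, z = x$z), 4))
  invisible(x)
}

#' Group-level one-sample t-test on subject effect estimates
#'
#' @param z_values one z-transformed effect per subject.
#' @return list with `t`, `df`, `p` (two-tailed), `mean`, `n`.
#' @export
group_activation_test <- function(z_values) {
  n <- length(z_values)
  if (n < 2L) stop("need at least 2 subjects")
  if (stats::sd(z_values) == 0) {
    # degenerate but well-defined: identical values
    t <- if (mean(z_values) == 0) 0 else sign(mean(z_values)) * Inf
    return(list(t = t, df = n - 1, p = if (t == 0) 1 else 0,
                mean = mean(z_values), n = n))
  }
  tt <- stats::t.test(z_values, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = mean(z_values), n = n)
}
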