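# riskdeck

Risk-preference modelling and synthetic neuroimaging analysis for a
four-deck probabilistic card task.

## The problem

In a four-deck card task, every trial shows one card value (0, 5, ..., 100)
per deck; a hidden second card is drawn from the remaining values and the
trial is won if the shown value is larger. Decks A/B pay +100/-125 points,
decks C/D pay +50/-25, so the shown value fixes the win probability
`p = (# smaller values)/20` and the two deck families differ in stakes.
The scientific question this kind of design serves is how an individual's
*risk preference* — the weight placed on outcome variance — relates to
personality (novelty seeking, NS) and to brain activity associated with
risk prediction.

`riskdeck` implements the complete analysis chain for that question, and a
synthetic-data generator with known ground truth so every stage can be
validated end to end:

* **Decision model** — per-deck reward prediction
  `r̂ = pW − (1−p)L`, risk prediction (two-outcome variance)
  `Risk = p(1−p)(W+L)²`, mean–variance utility `U = r̂ + l·Risk` with
  `l ∈ [−1, 1]`, softmax choice probabilities, and Shannon-entropy choice
  difficulty.
* **Model fitting** — maximum-likelihood estimation of `l` (1000-point
  grid + seeded golden-section refinements), per-trial MLL, AIC/AICc/BIC
  under an explicit group-size convention, argmax prediction accuracy, and
  model-vs-random-agent comparison tables.
* **Synthetic cohort** — uniform-random and softmax agents; ~30-subject
  cohorts whose integer NS scores (0–34, mean 14.57, SD 3.81) correlate
  with risk preference (mean −0.15, SD 0.27) at a configurable level;
  block-design task BOLD with NS-dependent risk modulation; 240-volume
  resting series with target inter-ROI correlations and injected motion
  spikes.
* **fMRI GLM** — parametric-modulation design matrices (risk, reward,
  entropy modulators, mean-centered per run), single-gamma HRF
  convolution, OLS with z-transformed effects, group one-sample t-tests.
* **Resting-state connectivity** — detrending, motion regression,
  FD > 0.5 mm scrubbing (Power-style), 0.01–0.08 Hz zero-phase band-pass,
  nuisance regression, pairwise Pearson r and Fisher z.
* **Group statistics** — Pearson and first-order partial correlations,
  Sobel mediation, explicit Bonferroni families.
* **Pipeline** — `run_pipeline()` chains all of the above from one seeded
  configuration and writes CSV/JSON reports.

## Worked example

```r
library(riskdeck)

# a task sequence and a simulated risk-averse agent
task  <- generate_task_sequence(180, seed = 1)
agent <- simulate_model_agent(task, l = -0.4, seed = 4)
fit   <- fit_risk_preference(agent, search_config(seed = 3))
fit
#> Risk-preference fit: l_hat = -0.3022, MLL = 1.2950 nats/trial, accuracy = 38.9% (180 trials)
total_score(agent$outcomes)
#> [1] 1975

# one trial's valuation under the fitted preference
val <- valuate_trial(c(70, 25, 60, 35), params = model_params(fit$l_hat))
round(val$probabilities, 3)
#>     A     B     C     D
#> 0.288 0.131 0.312 0.269
round(val$entropy, 3)    # choice difficulty, max = log(4) = 1.386
#> [1] 1.341
```

The fitted `l_hat` lands near the generating value (the estimator's
sampling spread at 180 trials is roughly 0.25–0.3), the MLL sits below the
uniform-chance floor of `log(4) ≈ 1.386`, and the risk-averse agent
prefers the low-stakes decks C/D over the same-value deck A.

A full synthetic study — 30 subjects, behavioural fits, task GLM,
resting-state connectivity, group statistics — runs in a few seconds:

```r
rep <- run_pipeline(pipeline_config(n_random_agents = 50, seed = 42))
rep$table1
#> Goodness of fit: model agents (n = 30 ) vs uniform-random agents (n = 50 )
#>   MLL     1.31+/-0.03    1.45+/-0.03  t =   -20.14  p = 1.24e-32
#>   AIC     4.62+/-0.06    4.89+/-0.06  t =   -20.14  p = 1.24e-32
#>   AICC    4.76+/-0.06    4.97+/-0.06  t =   -15.70  p = 7.47e-26
#>   BIC     6.02+/-0.06    6.80+/-0.06  t =   -58.23  p = 4.83e-66
rep$cor_ns_l                                 # NS vs fitted risk preference
#> r = 0.599, p = 0.0004691 (n = 30, adjusted alpha = 0.05) *
rep$activation[["r_PI"]]$correlation         # NS vs risk activation (4-ROI family)
#> r = -0.611, p = 0.0003357 (n = 30, adjusted alpha = 0.0125) *
rep$partial[["r_PI"]]                        # ... controlling risk preference
#> r = -0.471, p = 0.009863 (n = 30, adjusted alpha = 0.0125) *
rep$rsfc[["r_striatum-r_PI"]]                # NS vs connectivity (6-pair family)
#> r = -0.422, p = 0.02003 (n = 30, adjusted alpha = 0.008333)
rep$mediation
#> Sobel mediation: a = -0.024 (SE 0.009), b = 3.396 (SE 1.290)
#>   indirect = -0.0807, Sobel z = -1.901, p = 0.05733 (n = 30)
```

The signs mirror the generating configuration: NS correlates positively
with fitted risk preference and negatively with both the risk-related
activation and the r-PI connectivity. Model agents beat random agents on
every goodness-of-fit statistic.

See `vignettes/risk-preference-pipeline.Rmd` for the model, the payoff
scaling trade-off, the synthetic generator's assumptions, and all
numerical design choices.

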