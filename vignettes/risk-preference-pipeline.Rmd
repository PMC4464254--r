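---
title: "Modelling risk preference in a four-deck card task: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling risk preference in a four-deck card task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskdeck)
```

## The task and its generative rules

The package models a probabilistic card task with four decks (A-D). Every
trial shows one card value per deck, drawn from the arithmetic sequence
0, 5, ..., 100. The subject picks a deck; a hidden second card is then drawn
uniformly from the 20 universe values different from the shown one, and the
trial is won if the shown value is strictly larger. Decks A and B pay
+100/-125 points, decks C and D pay +50/-25. Because the second card can
never equal the first, ties are impossible and the win probability of a
shown value $x$ is simply the count of universe values below $x$ divided
by 20:

$$p(x) = \frac{\#\{v \in \{0,5,\dots,100\} : v < x\}}{20}.$$

Three constraints shape the stimulus stream: A and B never show the same
value within a trial (they share a payoff schedule), likewise C and D, and
no deck repeats its value on consecutive trials. `generate_task_sequence()`
samples uniformly from the admissible values under these constraints. The
second-card distribution (uniform over the 20 admissible values) is the
modelled generative rule; the task description only fixes the "never equal"
constraint, and uniformity is the natural maximum-entropy completion.

## The decision model

For each deck $i$ with scaled payoffs $W_i$ (win) and $L_i$ (loss
magnitude) and win probability $p_i$:

* reward prediction: $\hat r_i = p_i W_i - (1 - p_i) L_i$,
* risk prediction: the expected squared prediction error, i.e. the
  two-outcome variance $\mathrm{Risk}_i = p_i (1 - p_i)(W_i + L_i)^2$,
* utility: $U_i = \hat r_i + l \cdot \mathrm{Risk}_i$, with $l \in [-1, 1]$
  the subject's risk preference (negative = risk-averse),
* choice probabilities by softmax, $P_i = e^{U_i} / \sum_j e^{U_j}$
  (computed with max-subtraction for overflow safety),
* choice difficulty as the Shannon entropy $H = -\sum_i P_i \ln P_i$, which
  is maximal ($\ln 4 \approx 1.386$) when the four decks are equally
  attractive.

Nothing is learned across trials: the displayed value fully determines the
outcome distribution, so the model is static by design.

Risk enters as the variance, following the model's definition of risk as
the expected squared prediction error; a standard-deviation variant is
available (`model_params(risk_as_sd = TRUE)`) but off by default.

### The payoff scale

The softmax has no temperature parameter, so the scale on which payoffs
enter the utility *is* the effective choice sensitivity. Raw points would
put variances near $10^4$ and saturate the softmax; the package therefore
divides payoffs by `payoff_scale` before valuation. The default is 125, the
largest payoff magnitude, which makes all scaled payoffs at most 1 in
absolute value.

This choice matters, and pulls in two directions:

* **Goodness of fit of random choosers.** For choices made uniformly at
  random, the fitted model's per-trial mean negative log-likelihood (MLL)
  is bounded below by $\ln 4$ and decreases toward it as the scale grows,
  because larger scales flatten the utilities toward the uniform
  prediction. At the default scale the random-agent MLL is about 1.44-1.45
  nats/trial (the acceptance script computes it); reproducing a value as
  low as 1.39 would require roughly doubling the scale.
* **Identifiability of $l$.** The curvature of the likelihood in $l$ comes
  from the spread of the risk column, which shrinks quadratically with the
  scale. At the default scale the maximum-likelihood estimator of $l$
  recovers simulated agents with mean bias below 0.1 across the tested
  range (the test suite measures this); at twice the scale the estimator's
  sampling spread grows several-fold and boundary truncation biases the
  recovered values badly.

These two desiderata cannot be satisfied by a single scale under this
stimulus generator: near-flat utilities and an informative likelihood are
mutually exclusive. The package resolves the conflict in favour of
identifiability, because every downstream analysis (parameter recovery,
NS correlations, mediation) depends on meaningful per-subject estimates,
while the random-agent fit statistics are a descriptive baseline. The scale
remains a single configurable number for users who want the opposite
trade-off.

## Maximum-likelihood estimation

`fit_risk_preference()` maximizes
$\sum_t \ln P_{i_t}(t)$ over $l \in [-1, 1]$ with a two-stage search: an
even 1000-point grid followed by four seeded golden-section refinements
inside randomly chosen high-likelihood grid neighbourhoods (the best grid
point is always refined). Exact likelihood ties are broken toward the
smallest $|l|$, preferring the least extreme explanation. The test suite
checks the search against a $10^5$-point brute-force grid; agreement is
within one grid step.

Reported statistics follow a per-trial, group-size convention:

* MLL $= -\mathrm{LL}/n_{\text{trials}}$ (nats/trial), so a uniform
  predictor scores $\ln 4 \approx 1.386$ regardless of length;
* AIC $= 2k + 2\,\mathrm{MLL}$ with $k = 1$ free parameter;
* AICc adds $2k(k+1)/(M - k - 1)$ and BIC is $k \ln M + 2\,\mathrm{MLL}$,
  where $M$ is the *number of datasets in the comparison group*, not the
  number of trials.

Using the group size in the sample-size terms is unusual; it is implemented
because it is the convention under which the reference group statistics are
internally consistent (for example, with 1000 random datasets,
BIC $-$ 2 MLL $= \ln 1000 \approx 6.91$). `information_criteria()` takes
$M$ explicitly so the conventional per-trial variant is one argument away.

Prediction accuracy is the fraction of trials whose argmax-probability deck
matches the observed choice, with exact ties resolved toward the lowest
deck index. For uniform-random choosers the expected accuracy is exactly
25% by symmetry; the acceptance suite verifies both the analytic value and
the simulated mean.

## The synthetic cohort

`generate_cohort()` draws latent standard-normal pairs with correlation
`rho_ns_l` (default 0.555), maps one coordinate to an integer
novelty-seeking (NS) score on the 0-34 questionnaire scale (mean 14.57,
SD 3.81, rounded and clipped) and the other to a risk preference (mean
-0.15, SD 0.27, clipped to $[-1,1]$), then simulates each subject's 180
trials from the softmax model at that subject's $l$. Rounding and clipping
attenuate the realized correlation slightly, so the achieved value is
recorded on the cohort rather than forced.

Task BOLD series are simulated per subject as
$y = X\beta + \varepsilon$ with the package's own design matrix (below) and
AR(1) Gaussian noise ($\rho = 0.3$ by default). The risk-modulation
amplitude $\beta_{\text{risk}}$ varies across subjects with a configurable
correlation to NS (default $-0.51$); reward and entropy amplitudes are
constant. Resting-state series are band-limited (0.01-0.08 Hz) Gaussian
processes mixed to a target inter-ROI correlation matrix via its Cholesky
factor, plus white measurement noise; the NS effect enters on the Fisher-z
scale of the r-PI pair correlations (default $-0.511$). Motion tables are
zero except for injected displacement steps, so framewise displacement
exceeds threshold at exactly the scheduled volumes.

What the generator does *not* emulate: image space (ROIs are time-series
channels, not voxels), physiological noise structure beyond AR(1)/band-
limited Gaussian, reaction times, learning, and the original study's fixed
pseudo-random stimulus sequence, which was never published. Passing tests
therefore demonstrate the correctness and calibration of the pipeline on
data whose generative assumptions match the model - not that the model
describes human choices.

### Timing layout

Each scanning run is 30 s rest + 3 x (20 trials x 5 s + 30 s rest)
= 420 s = 210 volumes at TR 2 s; three runs hold the 180 trials. Trials run
back-to-back (4 s choice + 1 s outcome, no inter-trial interval), and the
rest block is placed at the run start so that the printed 7-minute run
length is exact. The resting-state scan is 240 volumes (8 min).

## Parametric-modulation GLM

`build_design()` places one impulse per trial at the trial onset, scaled by
the trial's model quantity (risk prediction and reward prediction of the
chosen deck, and the trial entropy), mean-centers each modulator within run
to decouple it from the run baseline, convolves with a single-gamma HRF

$$h(t) = \left(\frac{t}{pq}\right)^p e^{\,p - t/q}, \qquad p = 8.6,\;
q = 0.547,$$

(unit peak near 4.7 s, back under 1% of peak by 25 s) and samples on the TR
grid. The run baselines enter as per-run indicator columns; six motion
columns are optional. Modulators are mean-centered rather than
orthogonalized against each other - both the HRF parameters and the
centering flag are exposed because neither is dictated by the modelled
recipe. `fit_glm()` is ordinary least squares with
$z = \hat\beta / \mathrm{SE}$ as the subject-level effect
("z-transformed beta"); rank deficiency is reported naming the offending
columns rather than silently dropped.

## Resting-state connectivity

`rsfc_pipeline()` applies, in fixed order: linear+quadratic detrending;
regression of the six motion parameters; scrubbing of volumes with
framewise displacement above 0.5 mm (Power-style FD: absolute backward
differences of three translations plus three rotations converted to arc
length on a 50 mm sphere - the radius is the method's standard and is
configurable); band-pass 0.01-0.08 Hz; optional nuisance regression
(e.g. white-matter/CSF averages supplied as columns); then Pearson
correlation over retained volumes and Fisher z. Scrubbed volumes are
linearly interpolated before filtering and dropped afterwards, so spike
energy does not leak through the filter; setting `interpolate = FALSE`
filters the raw series instead, and the two choices measurably differ.

The band-pass is an ideal zero-phase Fourier-domain filter (frequency bins
outside the band, including DC, are zeroed). At 240 volumes and TR 2 s a
finite-impulse-response filter sharp enough at the 0.01 Hz edge would need
an order comparable to the series length, whereas the Fourier filter has
exact pass- and stop-band behaviour; this is the same approach used by
standard fMRI band-pass tools. More than 10% scrubbed volumes raises a
warning and more than 50% is an error, mirroring the usability bounds
reported for this recipe.

## Group statistics

`pearson()` wraps the product-moment correlation with two-tailed t-based
p-values; `partial_correlation()` implements the first-order formula
$r_{xy \cdot z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1 - r_{xz}^2)(1 -
r_{yz}^2)}$ with $n - 3$ degrees of freedom (the test suite asserts its
identity with the residual-residual Pearson correlation);
`sobel_mediation()` fits the Baron-Kenny chain by least squares and tests
the indirect effect with $z = ab / \sqrt{b^2 SE_a^2 + a^2 SE_b^2}$. All
p-values are two-tailed. Bonferroni families are explicit: each report
carries the family size and adjusted alpha (0.05/4 for the partial
correlations, 0.05/6 for the six ROI pairs), and the significance flag is
recomputable from them. The mediation direction (X = activation,
M = risk preference, Y = NS) is configuration, not hard-coded, because the
directional analysis it mirrors is not fully specified in the available
material; bootstrap mediation is deliberately out of scope.

## The pipeline

`run_pipeline()` chains everything from a single seeded
`pipeline_config()`: task sequence, cohort, per-subject MLE, random-agent
comparison group (a Table-1-style summary via `make_table1()`), task BOLD
simulation and GLM per ROI (the analysis design uses each subject's
*fitted* $l$, while generation uses the true $l$, as in a real analysis
where the truth is unknown), resting-state simulation and cleaning, and the
group statistics. Every stage derives its seed from the global seed, so the
whole report is reproducible; `write_report()` serializes the subject
table, Table-1 analogue, all correlation reports and a JSON bundle.

## Numerical choices and degenerate inputs

* Softmax and entropy use natural logarithms throughout; $0 \ln 0 = 0$.
* The MLE tie-break (smallest $|l|$) and the argmax tie-break (lowest deck
  index) are deterministic and documented; ties are only reachable with
  symmetric custom payoffs.
* `scrub()` refuses series with more than half the volumes flagged;
  `seed_connectivity()` requires 30 usable volumes and refuses
  self-connectivity.
* Zero-variance inputs to correlations and collinear covariates raise
  errors naming the problem instead of returning NaN.
* Problem sizes in the test suite (200 random datasets, 200 agents per
  recovery point, 2000 null GLM simulations, 100 pipeline seeds at
  $n = 30$) were chosen as the smallest sizes at which the Monte-Carlo
  error of each checked quantity is well below its tolerance.

## Known limitations

* The original stimulus sequence is unpublished and was evidently not
  uniform over card values (its random-agent total scores sit far above
  the uniform expectation), so quantities tied to that sequence - total
  scores, and in part the random-agent fit statistics - are not exactly
  reproducible under this generator.
* Participant-level behavioural statistics (high prediction accuracy, low
  MLL) would require choice data sharper than the softmax at the default
  scale produces; the synthetic cohort is a model-consistent population,
  not a re-creation of the human sample.
* ROI time series stand in for localized clusters; no spatial inference,
  segmentation or registration is modelled.
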