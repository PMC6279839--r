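---
title: "Modelling patient–ventilator asynchrony counts with Poisson hidden Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling patient-ventilator asynchrony counts with Poisson hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvahmm)
```

## The model

Breath-by-breath monitoring of a mechanically ventilated patient yields,
after indexing, a discrete time series $x_1, \dots, x_n$ of asynchrony
event counts per window of $T$ minutes ($T = 15$ by default), together
with an exposure series $n_t$ (respiratory cycles per window). These
series are non-negative, heavily zero-inflated at the patient level and
positively skewed, with occasional long excursions to very high counts —
the signature of a process that switches between persistent regimes.

`pvahmm` models this with a $K$-state hidden Markov model with Poisson
emissions. A latent chain $z_t \in \{1, \dots, K\}$ follows
$\Pr(z_1 = j) = \pi_j$ and
$\Pr(z_{t+1} = k \mid z_t = j) = A_{jk}$, and counts are conditionally
Poisson, $x_t \mid z_t = j \sim \mathrm{Poisson}(\lambda_j)$. States
are labelled in increasing order of $\lambda$, so state 1 is a
very-low-risk regime (near-perfect patient–ventilator interaction) and
state $K$ a very-high-risk one. $K = 4$ is the default: it matches the
clinical reading of the series as very-low / low / high / very-high
risk, and four well-separated means cover the observed dynamic range.
The model deliberately has no covariates and a single shared parameter
set across patients; heterogeneity is absorbed by the state process.

Assumptions worth stating: counts in different windows are independent
given the states (no within-window autocorrelation beyond what the
chain carries); the emission is equidispersed Poisson per state —
marginal overdispersion is produced by the state mixture, not by the
emission family; and windows are homogeneous in exposure, which is why
the indexer drops trailing partial windows rather than rescaling them.

## Fitting

`fit_poisson_hmm()` maximises the likelihood by EM (Baum–Welch). The
E-step runs scaled forward–backward recursions (implemented in C++ via
Rcpp; per-window max-shifting of the log emissions keeps the recursion
stable for series beyond $10^5$ windows and means up to $10^3$). The
M-step is in closed form:
$\lambda_j = \sum_t \gamma_t(j) x_t / \sum_t \gamma_t(j)$, transition
rows are normalised expected transition counts, and $\pi$ is the
average first-window posterior. Several sequences (patients) are pooled
by summing sufficient statistics, giving one model for the whole
cohort; `method = "average"` instead fits each sequence separately and
averages the canonically ordered parameters, the convention matching a
per-patient-average transition summary.

Tunable parameters, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `K` | 4 | risk states (see above) |
| `n_restarts` | 10 | random EM restarts; best final log-likelihood wins |
| `tol` | 1e-6 | relative log-likelihood change declaring convergence |
| `max_iter` | 500 | cap per restart |
| `level` | 0.95 | count-interval and predictive-interval coverage |

Initialisation matters in skewed count data. $\lambda$ is initialised
from quantiles of the observed non-zero counts with multiplicative
log-normal jitter, $\pi$ uniform, and $A$ diagonal-heavy (0.8). The
first restart uses evenly spaced quantile positions; later restarts
randomise the positions themselves. The randomisation is the point:
with fixed positions, every jittered start lands in the same basin and
EM can converge to a merged-state optimum (two high states fused, one
low state split) in every restart simultaneously — randomised positions
make the restarts explore genuinely different basins, at no cost when
the evenly spaced start is already good. Numerical floors
($\lambda \ge 10^{-6}$; transition entries $\ge 10^{-12}$ before row
normalisation) keep degenerate inputs (e.g. all-zero series) from
producing $\log 0$; such fits carry a warning.

Convergence is declared when the relative log-likelihood change drops
below `tol`; the trace is stored per restart and is non-decreasing
within each (tested to $10^{-8}$). After fitting, states are relabelled
so $\lambda_1 < \dots < \lambda_K$; every reported quantity is
invariant to the arbitrary labelling of the initialisation.

## Decoding, intervals, forecasting

`decode_states()` returns the smoothed posteriors $\gamma_t(j)$ and the
Viterbi path (computed in log space; ties break to the lower state).
The per-state *time spent*, tspent, is reported both as Viterbi
occupancy — the headline convention, because it reflects the single
coherent state trajectory a clinician would be shown — and as the mean
smoothed posterior; the two agree closely whenever the states are well
separated.

`credible_interval()` summarises each state's count distribution by the
equal-tailed interval from the exact Poisson quantile function: the
lower endpoint is the smallest $k$ with $F(k) \ge (1-\text{level})/2$
and the upper the smallest $k$ with $F(k) \ge 1-(1-\text{level})/2$. No
normal approximation is involved, which matters at small means: a state
with $\lambda = 1$ has 95% interval $(0, 3)$. Equal-tailed rather than
highest-density intervals are an interpretive choice; the two coincide
at small $\lambda$ and differ by about one count at $\lambda \approx
120$.

`forecast_one_step()` propagates the filtered state distribution one
step, $p_{t+1} = \hat\alpha_t A$, and summarises the Poisson mixture
$\sum_j p_{t+1,j}\,\mathrm{Poisson}(\lambda_j)$: expected count
$\sum_j p_{t+1,j} \lambda_j$ and an equal-tailed predictive count
interval from the exact mixture CDF. The mixture is skewed, so the
expectation need not be central in the interval. On simulated data the
95% predictive intervals cover the realised next count at nominal rate
(the suite checks coverage in [92%, 98%] at $n = 2000$).
`risk_state_probability()` sums the tail of the forecast simplex — the
quantity an alarm would threshold when a patient may be entering a
high-event regime.

## Rates

Counts are hard to compare across windows of different breathing rates,
so `state_rates()` converts each state's mean count into an approximate
rate (% of respiratory cycles). The exposure per state is estimated by
a log-link Poisson intercept model of breaths per window evaluated per
decoded state (its fitted value is the per-state mean exposure), and
the rate is $100\,\lambda_j/\widehat{\text{exposure}}_j$. This is the
simplest model consistent with "event counts divided by respiratory
cycles per window", and it makes the rate invariant to the window
length when the underlying per-breath event probability is fixed
(tested). Printed rate tables from bedside cohorts cannot be reproduced
from the model alone — they require the cohort's true per-state breath
counts, which are not part of a fitted model; on synthetic data with a
known per-breath event probability the estimator recovers $100p$ within
Monte-Carlo error.

## Evaluation

`kfold_cv()` (default $k = 5$) partitions *patients* — never windows —
into folds with a seeded shuffle, fits on $k-1$ folds and produces
one-step-ahead forecasts for every window $t \ge 2$ of the held-out
patients by filtering with frozen parameters. Forecasts start at
$t = 2$ because the first window has no history, and the zero-count
base model (predict 0 events always — the single most likely outcome
in these series) is scored on the identical index set. Per-fold RMSE
pools all held-out windows, the variance-minimising convention; the
summary reports means and $\mathrm{SD}/\sqrt{k}$ standard errors. On
cohorts simulated from a persistent multi-state chain the HMM beats
the base model in at least 19 of 20 seeded replicates — the ordering,
not any particular RMSE value, is the transportable claim, since
absolute RMSE depends entirely on the cohort's count scale.

## The synthetic generator

Because bedside asynchrony datasets are not publicly available, the
package carries a first-class generator whose defaults *are* the study
conditions the rest of the package is tested under:

- `make_persistent_matrix(stationary, persistence)` builds a
  birth–death (tridiagonal) transition matrix satisfying detailed
  balance $\pi_i A_{i,i+1} = \pi_{i+1} A_{i+1,i}$, so the requested
  stationary law holds analytically; rates are scaled so the least
  persistent diagonal equals `persistence` (default 0.85, the observed
  order of persistence of the lowest-risk state). Birth–death structure
  encodes the empirical fact that risk states switch almost exclusively
  to neighbours.
- State means default to 1, 11, 38 and 119 events per 15-minute window
  and the stationary law to 0.52/0.28/0.14/0.06 — the published
  operating point of the four-state model this package re-implements.
- Exposure defaults to 330 breaths per 15-minute window (22/min, a
  typical ventilated respiratory rate).
- `simulate_breaths()` places a Poisson number of breaths uniformly in
  each window and draws independent per-type flags (ineffective
  effort, double/short/prolonged cycling) at per-breath, per-state
  probabilities, so the indexing stage can be round-trip tested against
  the generator's own bookkeeping.
- `simulate_cardio()` draws within-window HR/SpO2 samples from
  state-conditional Gaussians (HR mean 85, SD 12 bpm in every state —
  heart rate is empirically similar across risk states; SpO2 means
  96.5/96/95.5/93, SD 2.5%, clamped to (0, 100]). The SpO2 profile is
  chosen so hypoxemia (SpO2 < 90%) becomes markedly more frequent in
  the top state while remaining overlapping elsewhere — the ordinal
  pattern is the claim, not the magnitudes.

What the generator does *not* emulate: raw 200-Hz airway
pressure/flow waveforms (flags are taken as given), non-stationary
drift of a patient's parameters over days, exposure that varies with
state, and non-Gaussian cardio noise. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
model, not clinical validity on real waveform-derived data.

## Indexing conventions

Windows are half-open $[\mathrm{origin} + kT, \mathrm{origin} +
(k+1)T)$ with the origin defaulting to the first breath's timestamp
truncated to the whole minute; a boundary breath belongs to the later
window. The default counting mode counts *events* (a breath with two
asynchrony types contributes 2); `counting_mode = "breaths"` counts
affected breaths instead — both readings of "number of events per
window" are defensible, so both are implemented and the choice is
explicit. Trailing partial windows are dropped, and indexing at $T$
then aggregating triples of windows is exactly indexing at $3T$ (an
integer identity, tested). Cardio windows with no samples are missing,
never zero, and are excluded from episode statistics rather than
imputed; within-window episode durations treat samples as equally
spaced, the only defensible rule when no sample timestamps or
durations are available.

## Cardio episode statistics

`detect_episodes()` applies the clinical thresholds (bradycardia
HR < 60 bpm, tachycardia HR > 100 bpm, hypoxemia SpO2 < 90%) per
window; `state_matched_stats()` matches them to a decoded state path
and reports, per state and type, the percentage of windows with at
least one episode and the mean (SD) percent of window time in episode.
The analysis is purely descriptive — no significance testing, and no
causal claim that states produce episodes. States never visited by the
path yield `NA` statistics, not 0.

## Problem sizes and determinism

All simulation-backed checks in the test suite use sizes chosen to make
the Monte-Carlo error a small fraction of the tolerance being asserted:
20,000 windows for parameter-recovery checks (recovered $\lambda$
within 10%, transition entries within ±0.03, lowest-state occupancy
within ±5 points), 5,000 windows × 20 replicates for the recovery-rate
property, 2,000 windows for forecast calibration, and a 20-patient ×
150-window cohort × 20 replicates for the cross-validation ordering
property. Every stochastic function takes an explicit `seed` argument
scoped with `withr` — the global RNG stream is never consumed or
disturbed, and a fixed seed reproduces results bit-for-bit, including
`run_pipeline()`'s artifacts byte-for-byte.

## Known limitations

- Exposure enters the rate conversion but not the likelihood: the
  emission is $\mathrm{Poisson}(\lambda_j)$, not
  $\mathrm{Poisson}(n_t \rho_j)$. This mirrors the intercept-only
  design the package re-implements; an offset-HMM would be the natural
  extension.
- No covariates, no negative-binomial or zero-inflated emissions, no
  Bayesian posterior sampling.
- Model selection for $K$ is left to the user (`glance()` reports AIC
  and BIC); the default 4 is a clinical convention, not an estimate.
- The equal-tailed/HDI distinction at large $\lambda$ (about one count
  at $\lambda \approx 120$) is below the resolution of any decision a
  user would take from these intervals.
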