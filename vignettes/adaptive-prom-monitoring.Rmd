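---
title: "Adaptive PROM monitoring: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive PROM monitoring: models, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promcat)
```

This vignette is the package's account of its science: the measurement
model and the adaptive algorithm, the parameters that matter and their
defaults, what the synthetic-data machinery emulates (and what it does
not), and the numerical and design choices behind the implementation.

## Measurement model

Responses to polytomous PROM items are modelled with Samejima's graded
response model in slope–threshold form. Item $j$ has discrimination
$a_j > 0$ and strictly increasing thresholds
$b_{j,1} < \dots < b_{j,K_j-1}$; the probability of responding at or
above category boundary $k$ is logistic in $a_j(\theta - b_{j,k})$, and
category probabilities are adjacent differences of these curves. Two
conventions are fixed for reproducibility:

* the link is pure logistic — no 1.7 normal-ogive scaling constant is
  applied, so discriminations are on the logit slope scale;
* categories are numbered $1..K$ and thresholds $1..K-1$, matching
  ordinary PROM scoring sheets.

The latent trait $\theta$ is a z score: 0 is the mean of the
instrument's calibration sample, one unit is one calibration-sample SD,
and the bank's orientation flag records that higher means more severe.
Most patients fall in $[-2, 2]$.

Fisher information for an item is
$I_j(\theta) = \sum_k P_k'(\theta)^2 / P_k(\theta)$, which reduces to
the familiar $a^2 p (1-p)$ for a dichotomous item. The test checks this
closed form and validates the polytomous case against a
finite-difference second-derivative oracle.

## EAP scoring and its quadrature

Scoring is expected a posteriori: with prior $\pi$ and likelihood
$L(\theta)$ over the collected responses,
$\hat\theta = \int \theta L \pi \,d\theta / \int L \pi \,d\theta$, and
the SE of measurement is the posterior SD computed the same way. All
integrals use a fixed trapezoid grid — 161 equally spaced points on
$[-6, 6]$ (`quad_grid()`). The bounds are deliberately wider than the
usual $[-4, 4]$: dynamic priors can park substantial posterior mass
well away from zero, and a narrow grid would truncate it. At 161
points the grid error on EAP and SE is below $10^{-4}$ against a
10,001-point reference, which the test suite verifies directly; the
cost of the denser default is negligible because category-probability
matrices are cached per bank.

Likelihood accumulation happens in log space and, importantly, in
*bank order* regardless of administration order. This makes the
posterior arithmetic order-invariant, so an adaptive assessment that
happens to exhaust the bank reproduces the full-length score
bit-for-bit — a property the tests assert with `expect_identical()`.

Credible intervals use the normal approximation
$\hat\theta \pm 1.959964\,\mathrm{SE}$ with the multiplier fixed at
that value (not recomputed from `qnorm`) so that interval arithmetic
is stable across platforms.

A degenerate posterior — zero density at every grid point, which can
only arise from contradictory near-deterministic responses — raises an
error rather than returning NaNs.

## Item selection and stopping

The default selector is minimum expected posterior variance. For each
candidate item the engine computes the posterior-predictive
probability of each category and the posterior variance that would
result from observing it; the item minimizing the weighted average is
posed next. By the law of total variance the criterion value never
exceeds the current posterior variance, which doubles as a cheap
internal consistency check (and a test). Maximum information at the
current EAP is available as an alternative, and both support
*randomesque* exposure control: drawing uniformly among the $n$
top-ranked items, which spreads item usage at a small efficiency cost.
Ties are broken by lowest bank index so that selection is fully
deterministic at `randomesque_n = 1`.

Stopping is precision-targeted: terminate once the SE of measurement
drops below 0.3, equivalent to a marginal reliability of
$1 - 0.3^2 = 0.91$ on the unit-variance scale. Two guards complete the
rule: a minimum of one item per assessment — so a respondent whose
carried-over prior is already tighter than the threshold still answers
something, and zero-item assessments cannot occur — and a maximum-item
cap defaulting to the bank size. Reasons (`se_met`, `max_items`,
`bank_exhausted`) are recorded per assessment.

## Dynamic priors

The first assessment of a respondent uses the standard normal prior
$N(0, 1)$ — the population-level statement that, before any data, the
respondent resembles the calibration sample. Each subsequent
assessment uses the *normal approximation* to the previous completed
posterior, $N(\hat\theta_{\text{prev}}, \mathrm{SE}_{\text{prev}}^2)$,
rather than carrying the raw gridded density. The normal approximation
was chosen because it matches the credible-interval convention used
everywhere else in the package, keeps priors closed-form and
serializable in two numbers, and empirically loses almost nothing: a
post-assessment posterior after several graded items is already close
to normal. Carrying the raw density is a possible extension.

Two numerical details: the prior SD is floored at 0.1 so that a long
chain of dynamic updates cannot collapse the prior to a spike, and the
floor is applied *before* the optional between-occasion variance
inflation, so an inflated prior is always at least
$\sqrt{0.1^2 + \text{inflation}^2}$ wide. The default inflation is 0;
a positive value is the natural knob when symptoms are expected to
move quickly between occasions.

The efficiency gain is what makes high-frequency administration
tolerable: starting cold, reaching SE < 0.3 on the synthetic bank
takes most of its 11 items, while a dynamically primed assessment
typically needs one or two. The test suite checks the paired property
(dynamic never needs more items on average than static on the same
seeds).

## The synthetic bank and what it emulates

No public calibration exists for the kind of registry-derived item
parameters this engine is designed to consume, so the package ships a
*synthetic* bank (`simulate_item_bank()`, also materialized at
`inst/extdata/synthetic_bank.csv`) that emulates the structure of an
11-item hand-function PROM with 7 response categories: discriminations
drawn once from $U(1.5, 2.5)$ under a fixed generation seed, and
per-item thresholds equally spaced at 0.7 logits around midpoints
spread evenly over $[-2, 2]$. This yields a bank whose information is
spread across the clinically occupied range, with moderate
discriminations typical of ordinal symptom items.

What the synthetic bank does *not* emulate: the idiosyncratic
information profile of a real calibrated instrument, where one or two
items dominate at common severity levels and adaptive selection
concentrates on them. Consequences for interpretation: simulated
items-per-assessment under a cold prior (median around 9–10 here) are
an upper bound relative to a sharply calibrated real bank, and item
exposure is more even. Conclusions from the test suite about score
agreement, stopping soundness and prior efficiency are structural —
they do not depend on which items happen to be informative — but
absolute item counts should not be read as predictions for a specific
instrument.

## The EMA simulator

`ema_regime()` generates the three prescheduled frequencies — thrice
weekly (Mon/Wed/Fri), daily, thrice daily — over a 12-week default
window: 36, 84 and 252 occasions respectively. Clock times are not
something a schedule can avoid, and 09:00 (daily), 09:00/14:00/20:00
(thrice daily) are plausible waking-hours defaults; both are
configurable.

Simulated respondents (`sim_respondent()`, `simulate_cohort()`) couple
a latent trajectory with behaviour:

* **Recovery** trajectories decay exponentially from a baseline toward
  an asymptote — the shape expected after an injury with a good
  prognosis. Defaults place baselines in $U(0, 1.8)$, asymptotes in
  $U(-1.8, -0.5)$ and rates in $U(0.03, 0.08)$ per day, so most
  simulated patients improve by one to three z units over 12 weeks.
* **Fluctuating** trajectories add to a stable baseline a sinusoidal
  diurnal swing (severity peaking in the evening), stationary AR(1)
  occasion noise ($\rho = 0.7$, innovation SD 0.25), and optionally an
  intervention dip: severity falls linearly to `depth` below baseline
  over the first half of the rebound window and returns linearly to
  baseline by its end (10 days by default) — the washout course of a
  steroid injection.
* **Compliance** is an independent Bernoulli per occasion, defaulting
  by arm to 0.93 (daily), 0.63 (thrice weekly) and 0.43 (thrice
  daily) — the ordering such deployments observe: daily prompts become
  routine, very frequent prompts fatigue.
* **Response delay** is log-normal with median 54 minutes and log-SD
  2.1 (IQR roughly 12 minutes to 3.5 hours). It timestamps records and
  affects no scores.

The default cohort is 39 respondents (12/15/12 across the arms),
alternating recovery and fluctuating profiles within each arm.
`run_study()` chains assessments with dynamic priors per respondent,
optionally administers the full bank at weeks 0, 6 and 12 — reusing
the same-day latent value so paired comparisons measure the same
momentary state — and emits tidy response-log and summary tables.
`compare_cat_full_length()` pairs same-day records and reports mean
signed error, MAE, RMSE and correlation; the correlation is flagged
`NA` when degenerate (fewer than two pairs or zero variance).

What the simulator does not model: informative missingness
(compliance is independent of severity), notification delivery, recall
effects, response styles, and item-parameter drift. Passing tests
therefore demonstrate the engine's internal validity — score recovery,
stopping soundness, efficiency — under a well-specified generative
model, not robustness to those human factors.

## Trajectory analytics

Each completed assessment yields $(\hat\theta, \mathrm{SE})$;
the analytics layer turns a respondent's series into displays that
keep individual-level measurement error visible:

* `credible_band()` — per-point intervals
  $\hat\theta_i \pm z\,\mathrm{SE}_i$ (95% default).
* `density_surface()` — the full gridded posterior per occasion,
  stacked into a time × $\theta$ matrix with every slice renormalized
  to integrate to 1; dark ridges mark where the true severity most
  plausibly lies.
* `loess_smooth()` — locally estimated scatterplot smoothing of the
  EAP series: tricube-weighted local linear regression over the
  span-nearest neighbours, computed exactly (`stats::loess` with
  `surface = "direct"`), with a band
  $\mathrm{fit} \pm t_{0.975,\nu}\,\mathrm{se(fit)}$ using the fit's
  residual degrees of freedom $\nu$. Defaults span 0.75 and degree 1:
  degree 1 avoids endpoint oscillation on the short, irregular series
  EMA produces, and the span is the conventional default in the
  absence of instrument-specific tuning. Robustness iterations are 0.
  Degenerate inputs (exactly collinear or constant series) make the
  local solves singular; the implementation tolerates them — the fit
  reproduces the data, the band collapses — and muffles the solver's
  pseudoinverse warnings.
* `cohort_overlay()` — linear interpolation of every comparison series
  onto a common time grid, *within each series' observed range only*
  (no extrapolation), reduced to a pointwise min/median/max envelope.
  Min/median/max was chosen over quantile estimates deliberately:
  with cohorts of ~20 patients, estimated quantiles suggest a
  precision that is not there, while the envelope is an honest
  description of the observed band.

## Numerical choices, in one place

| Choice | Value | Why |
|---|---|---|
| Quadrature | 161 points, $[-6,6]$, trapezoid | supports off-centre dynamic priors; $<10^{-4}$ grid error |
| Credible multiplier | 1.959964 fixed | platform-stable 95% normal interval |
| Prior SD floor | 0.1 | prevents collapse under repeated dynamic updates |
| Floor vs inflation order | floor first | an inflated prior is never narrower than its inflation |
| Selection tie-break | lowest bank index | deterministic replay |
| Likelihood accumulation | log space, bank order | overflow-safe; order-invariant, exact full-bank equivalence |
| Stopping guard | `min_items = 1` | no zero-item assessments under tight priors |
| LOESS | span 0.75, degree 1, tricube, 0 robustness iterations | short irregular series; conventional defaults |
| RNG | explicit seeds everywhere; simulators take a master seed | bit-reproducible studies |

## Problem sizes

The shipped experiments are sized for a single CPU: the score-recovery
simulation uses 5,000 respondents (about a minute), the property
checks use banks of 5–11 items with fine-grid oracles at 10,001
points, and the study-level tests use cohorts of 2–6 respondents over
1–2 weeks. These sizes give Monte-Carlo standard errors comfortably
inside the asserted tolerances (the mean-error check at $n = 5000$
has an SE near 0.0012 against a 0.01 band).

## Known limitations

* Only the graded response model is implemented; partial-credit or
  nominal items would need a second probability kernel.
* Only the EAP estimator is exposed: maximum-likelihood and weighted
  likelihood estimation are out of scope, as is content balancing.
* Dynamic priors carry the normal approximation, not the raw density.
* Item parameters are taken as known and time-invariant; calibration
  and parameter drift are outside the package's remit.
* The compliance model is noninformative; trajectories and
  missingness are independent by construction.
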