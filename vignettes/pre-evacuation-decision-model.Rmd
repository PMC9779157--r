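---
title: "Modelling pre-evacuation decision timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pre-evacuation decision timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preevac)
```

## The problem

When an emergency begins in a crowded place, most people do not move at
once. The interval between the first cue (alarm, smoke, shouting) and the
start of purposeful escape — the pre-evacuation phase — is often a large
share of the total required safe egress time (RSET), yet most evacuation
software treats it as a fixed or externally assigned delay. `preevac`
models it as a sequence of decisions: in each short decision period a
waiting pedestrian either keeps watching or commits to escape.

## The decision model

A pedestrian escapes in period $t$ when the difference between their
subjective risk utility and the objective risk utility exceeds a personal
escape-selection threshold. Subjective and objective utilities are linear
in the same situational factors, so only the coefficient differences are
identifiable; the model therefore works directly with the latent index

$$
\eta_{it} = \beta_0
  + \sum_j \beta_j \, x_{ij}
  + c_{\mathrm{rcs}} \mathrm{RCS}_{it}
  + c_{\mathrm{dfd}} \mathrm{DFD}_{it}
  + c_{\mathrm{rnc}} \mathrm{RNC}_{it},
$$

where $x_{ij}$ are the coded personal attributes (age grade, gender,
education, familiarity time, group size, residence-distance zone, travel
mode — the personal risk tolerance, PRT) and the three situational factors
are standardized to the unit interval. With standard-normal latent noise
the per-period escape hazard is the probit probability, floored by a
natural-response rate $C$ (Abbott's correction):

$$
p_{it} = C + (1 - C)\,\Phi(\eta_{it}/\sigma).
$$

$\sigma$ is not identified separately from the coefficients in a probit
and is normalized to 1; the field is kept on the coefficient object so a
rescaled model can still be represented. $C$ is the fraction who respond
spontaneously regardless of the modelled stimulus; it is estimated from a
control group as a simple proportion with its binomial standard error
(`natural_response()`), and enters the likelihood as a plug-in constant
rather than a free parameter — jointly estimating $C$ with a nearly flat
probit part is poorly identified and the control group measures it
directly.

Periods are conditionally independent given the hazards, so the first
escape follows the discrete-time survival (first-passage) law

$$
P_i(t) = p_{it} \prod_{n<t} (1 - p_{in}), \qquad
P_i(\text{never}) = \prod_{n \le T} (1 - p_{in}),
$$

implemented in `first_passage()`. The panel log-likelihood
(`decision_loglik()`) factorizes into Bernoulli terms over
respondent-period rows; right-censored respondents contribute their
survival mass by default, and `censored = FALSE` restricts the likelihood
to observed escapes for comparison with formulations that omit censoring.

The staged (two-intercept) form of the calibrated model is exposed as a
cumulative shared-slope probit: `stage_probabilities()` maps ordered
intercepts $\tau_1 \le \dots \le \tau_K$ and a predictor $\eta$ to the
$K+1$ category probabilities $\Phi(\tau_k + \eta) - \Phi(\tau_{k-1} +
\eta)$. The number of intercepts is configurable; two reproduces the
published structure.

## Standardization of the situational factors

All three factors are graded L1–L4 and mapped to $\{1.00, 0.75, 0.50,
0.25\}$ (`standardize_level()`).

* **RCS** (risk categories and strength) is the standardized level of the
  event itself — for a fire, its declared level.
* **DFD** (distance from danger) bins the Euclidean distance to the
  source at 20/40/60 m. The printed bands leave the boundaries ambiguous;
  the package uses half-open bins $[lo, hi)$ so every distance maps to
  exactly one level, putting 20 m in L2 and 60 m in L4.
* **RNC** (reaction of the neighbourhood crowd) has only behavioural
  labels in the source grading; the package quantifies it as the fraction
  of agents within a configurable radius (default 10 m) who have already
  reacted, cut at quartiles: $f \ge 0.75$ is L1 down to $f < 0.25$ as L4.

A continuous mode (`continuous = TRUE`) bypasses the quantization — DFD
becomes $\max(0, 1 - d/80)$ and RNC the raw fraction — and is off by
default so that the default pipeline matches the four-level grading.

One ambiguity deserves a flag: the demonstration scenario declares a fire
of "Level 4" even though L4 is the *weakest* grade in the standardization
table. The package takes the table literally by default (level 4 → scale
0.25) and provides `invert_rcs = TRUE` to read declared levels in the
opposite order; both conventions are exercised in the tests.

## Calibration

`fit_decision_model()` maximizes the panel likelihood over the constant
and the requested covariates. Numerics:

* Damped Newton with the analytic gradient and Hessian; every step is
  line-searched (step halving) so the objective decreases monotonically;
  convergence is declared at gradient max-norm below `gtol` (default
  1e-8), with a 500-iteration cap.
* The plain probit likelihood ($C = 0$) is globally concave and is
  started from zeros. The corrected likelihood ($C > 0$) is **not**
  concave: it has a spurious boundary basin in which the probit part is
  driven to zero and all response is attributed to $C$. Quasi-Newton
  iterations from a cold start reliably fall into it. The fit therefore
  first solves the plain probit problem, shifts the constant to the
  corrected response scale ($\Phi^{-1}\!\big((\bar y - C)/(1 - C)\big)$
  replacing $\Phi^{-1}(\bar y)$), and runs the damped Newton iteration
  from there, which converges to the interior optimum in a handful of
  steps.
* Standard errors come from the inverse observed information at the
  optimum; Z, two-sided significance and 95% intervals follow. A
  constant covariate is rejected as non-identifiable rather than silently
  dropped.
* Screening is one-pass and off by default: with `screen = TRUE`,
  covariates with significance above `alpha` (default 0.05) are dropped
  and the model refit once, the procedure that excluded education in the
  published calibration. Non-significant but retained covariates are
  flagged either way.
* A Pearson-type statistic $\sum (y - \hat p)^2 / (\hat p (1 - \hat p))$
  over respondent-period rows is reported as a fit diagnostic. It plays
  the role of a grouped-data chi-square without reproducing any
  particular grouping, so it is not comparable to published grouped
  values.

With $C = 0$ and a single period the model *is* a textbook probit, and
the test suite holds the fit to within 1e-6 of an independently converged
`glm(..., family = binomial("probit"))` on identical data.

## The synthetic survey generator

The survey behind the published calibration (4527 questionnaires) is not
deposited, so `sample_population()` and `simulate_survey()` emulate it:
categorical attributes drawn independently per respondent (uniform over
categories unless specified — the source states no attribute
distribution or dependence structure, so none is invented), situational
levels drawn uniformly from the four standardized values, and a decision
panel over 6 periods by default, with escape drawn each period from the
model hazard and absorbing thereafter. Control-group respondents answer
once with probability equal to the natural-response rate alone.

Two coding choices follow the published variable table: the
residence-distance zone lists five bands, which the package codes 1–5
(the table prints only four codes, an apparent typo), and travel mode is
coded 1–7 and entered as a single numeric covariate, exactly as the
published regression treats it. Treating an unordered seven-way category
as numeric is statistically questionable; the coding layer would support
one-hot encoding, but the default reproduces the published treatment.

What the generator does *not* emulate: attribute dependence (e.g. age
correlating with travel mode), scenario-specific context distributions,
question-order or nonresponse effects. Passing parameter-recovery tests
therefore demonstrates that the estimation machinery is correct under the
stated model, not that the model describes any particular real crowd.

The recovery study in the acceptance suite uses 50,000 respondents over 6
periods with the published retained coefficients and $C = 0$ (the natural
rate being checked separately through the control-group estimate). The
three situational coefficients are unpublished; the package defaults them
to 1.0 on the standardized scales, and every simulated quantity is
conditional on that choice.

## The fire-scene simulation

`default_scene()` ships a 100 m × 60 m rectangle split into three equal
halls (origin zones 1–3) with exit nodes 4 and 5 and connections 1–2,
2–3, 1–4, 3–5; the source layout figure prints no dimensions, so these
are package choices, and all geometry is configurable through
`build_scene()`. The fire sits at the centre of Zone 3 with a circular
smoke front growing at 0.3 m/s that walls do not block. Demand is split
14.3% / 28.6% / 57.1% across the origins by largest-remainder
apportionment and agents are scattered uniformly within their halls.

Each decision period (default `dt` = 1 s, 300 periods — the source states
no period length, and the 36 s figure there is a reporting interval, not
a decision step), every waiting agent recomputes its context from the
geometry, evaluates the hazard and draws a Bernoulli decision; escape is
absorbing. Agents do not move before escaping: the package models the
pre-evacuation phase only, and locomotion to exits is deliberately out of
scope.

The natural-response floor needs care here. Applied every period, a
per-second floor of 0.1981 empties any scene within ~20 s — a geometric
race that contradicts the wait-and-see dynamics the simulation exists to
study. The rate is defined as the fraction who respond *immediately* upon
perceiving the event, so the default (`natural_mode = "first_period"`)
applies it in the first decision period only; `"every_period"` and
`"none"` are available for comparison. An optional awareness delay
(`awareness_delay = TRUE`, off by default) keeps an agent's hazard at
zero until the smoke front reaches its zone.

A published narrative figure of roughly 20% escaping within 20 s depends
on unprinted geometry, population size, period length and the three
unpublished context coefficients; the package treats it as qualitative
corroboration only. The quantitative validation of the simulator is
internal: on a homogeneous population with frozen context, empirical
escape-period frequencies over 200 seeded replicates must match the
analytic first-passage law within four binomial standard errors per
period — a check the acceptance suite runs.

## Reproducibility and problem sizes

All randomness descends from one top-level seed through named substreams
(`substream_seed()`), so the population, survey and simulation stages
stay decoupled. Runs triggered through the config-driven entry points
(`cli_generate()`, `cli_fit()`, `cli_simulate()`, or the `preevac` script
under `inst/cli/`) write a provenance record (resolved config, its MD5,
seed, package version) beside every artifact.

The test suite works at sizes chosen to keep sampling noise well inside
the asserted bounds while remaining quick: 50,000 respondents for the
recovery study, 12,000 simulated chains for the simulator-vs-analytic
check, horizons of at most 6 periods for the exhaustive first-passage
enumeration (2^6 outcome paths per sequence).

## Known limitations

* Natural response is a plug-in, not jointly estimated; its sampling
  error is not propagated into the coefficient standard errors.
* The situational coefficients default to 1.0 for lack of published
  values; simulations are conditional on them.
* Mode-as-numeric inherits the published model's coding; the effect
  estimate for it has no natural unit interpretation.
* No post-decision movement, congestion or exit choice; no fire physics
  beyond the linear smoke front.
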