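---
title: "The effect model: estimation, simulation and decision methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The effect model: estimation, simulation and decision methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effectmodel)
```

## The effect model

For one disease, one clinical event and one treatment, observed over a
fixed follow-up, the effect model is the relationship between the event
risk without treatment (Rc) and with treatment (Rt). Plotted on the L'Abbé
plane — each randomized trial, or each patient, as an (Rc, Rt) point — the
diagonal `Rt = Rc` separates net harm from net benefit. The relationship is
a property of the disease–event–treatment triplet, not of any one trial,
which is why trial-average indices (relative risk, odds ratio, a single
NNT) are poor benchmarks for individual decisions: the absolute benefit
`AB = Rc − Rt` varies with the patient's untreated risk.

This package estimates the effect model two independent ways — statistical
fitting of trial summaries, and deterministic simulation of a mechanistic
therapy model over a virtual population — and derives the decision
quantities both support: per-patient AB and NNT, the number of prevented
events for a population, natural and budget-imposed treatment thresholds.

## The linear (statistical) model

`fit_effect_model()` fits `Rt = a·Rc + b` by weighted least squares of the
treated-arm event frequency on the control-arm frequency, one point per
trial. The slope `a` carries the beneficial, risk-proportional part of the
effect; the intercept `b` a constant adverse effect. Three weighting
schemes are offered; the default is inverse variance of the response,
`w = n_t / (p_t (1 − p_t))`, with a continuity correction
(`events + 0.5`, `n + 1`) inside the weight when a treated arm has zero or
all events, so no trial receives infinite weight. The reported risks
themselves are never corrected.

Design choices worth making explicit:

* **Rc is treated as fixed.** Both axes are estimated frequencies, so the
  regression is a naive errors-in-variables fit. With small trials the
  sampling noise in Rc attenuates the slope toward zero (regression to the
  mean). We keep the naive estimator deliberately — it is the classic
  summary-data approach — and surface the bias in a property test: with the
  same generating model (a = 0.56, b = 0.053), 40-trial meta-analyses at
  50 subjects/arm show a mean slope bias several times larger than at
  5,000/arm. Attenuation-corrected estimators are out of scope.
* **Intervals are normal-approximation at 95%** throughout; with 40 trials
  the empirical coverage in simulation lies in the low-to-mid 90s.
* **Polynomial comparison.** `compare_polynomial_fits()` scores degrees
  1…d by weighted RSS plus `2·(degree + 1)·σ̂²`, an AIC-like penalty with
  σ̂² taken from the most flexible candidate so all degrees are penalized
  on a common variance scale. Any monotone-in-fit criterion would do; this
  one correctly prefers degree 1 on line-generated data and degree ≥ 2 on
  data from the curvilinear closed form below.
* **Natural threshold.** For `0 < a < 1`, `b > 0`,
  `s = b/(1 − a)` is the unique fixed point of the fitted line. The
  function returns 0 when `b ≤ 0` (benefit at every risk) and `NA` when
  the line never crosses the diagonal inside (0, 1) — e.g. `a = 1` with
  `b ≠ 0` — rather than raising, so callers can fall back to AB-based
  rules.

## The mechanistic model

The therapeutic model follows a drug through six steps — absorption,
distribution, drug–receptor interaction, post-receptor transduction,
homeostatic feedback, and clinical transduction — with each step scaled by
one patient descriptor:

| step | form | patient descriptor |
|---|---|---|
| absorption/distribution | one-compartment oral PK; mean steady-state concentration `C̄ = F₀·x·D/(V·ke·τ)` | `x_absorption`; `x_age` scales `ke` by `clamp(age/50, 0.5, 2)` |
| receptor interaction | Hill: `S = Smax·C^γ/(EC50^γ + C^γ)` | `x_emax_genes` scales Smax; `x_binding_genes` scales EC50 |
| transduction | `Z = gain·x·S` | `x_transduction` |
| feedback | `E = Z/(1 + h·x·Z)` | `x_sympathetic` |
| clinical transduction | `risk = plogis(β₀ + β₁·y₁ + β₂·y₂ − E)` | `y_biomarker`, `y_risk_factor` |

Untreated risk Rc is the logistic at `E = 0`; treated risk Rt at the
subject's net effect, plus an optional constant iatrogenic risk
(`Rt = min(1, Rt_mech + harm)`). The harm term lives in the therapy
configuration, not the chain, so the pure-benefit mechanism and the
constant adverse effect compose explicitly — mirroring the separation of
`a` (benefit) and `b` (harm) in the linear model.

Choices and degenerate cases:

* **Exposure summary.** Risks over the follow-up are evaluated at the mean
  steady-state concentration of the dosing regimen, which makes Rc and Rt
  time-free given the regimen; a single-dose concentration profile
  `concentration()` is exposed separately (and checked against numerical
  ODE integration in the tests). The removable singularity at `ka = ke` is
  evaluated by its analytic limit `(F·D·ka·t/V)·e^(−ka·t)` when
  `|ka − ke| < 10⁻⁹·ka`.
* **Closed-form oracle.** Because the drug subtracts its effect from the
  logistic linear predictor, the event odds are multiplied by `e^(−E)`,
  giving `Rt = Rc/(Rc + (1 − Rc)·e^E)`. This curvilinear relationship is
  never coded into the simulation; with feedback off and unit transduction
  the simulated chain must land on it to machine precision, which the test
  suite verifies on a 50 × 50 subject-by-dose grid at 10⁻¹². The curve
  fixes 0 and 1, increases in Rc, decreases in E, and lies strictly below
  the diagonal — a pure-benefit model can only cross into net harm through
  the additive harm term.
* **Zero dose** collapses the entire chain to `Rt = Rc` exactly, for every
  subject.

## The virtual population

`sample_population()` draws independent subjects from per-descriptor
Normal or log-Normal distributions (log-Normals parameterized by the mean
and SD of the underlying normal; truncation by rejection sampling, capped
at 1,000 rounds). The shipped default — 200 subjects; multiplicative
descriptors log-Normal centred at 1 with SDs 0.25–0.40, age Normal(60, 10)
truncated to 30–90 years, Y descriptors standard normal, and logistic
coefficients `β₀ = −2, β₁ = 0.8, β₂ = 0.6` — emulates a cardiovascular
one-year-risk cohort with median untreated risk around 0.12 and a long
right tail, plausible for a post-infarction population. It is an
illustrative synthetic cohort, not calibrated to real data.

What the generator does *not* emulate: correlations between descriptors
(independence is the minimal assumption; the CSV reader accepts externally
built, possibly correlated populations without any downstream change),
within-patient variability, and time-resolved hazards (the follow-up is a
fixed window by design). Tests passing on this population therefore
demonstrate internal consistency of the machinery, not fidelity to any
real cohort.

Sampling is fully determined by the spec's seed and leaves the caller's
RNG stream untouched; population sizes of 200 (reference scatter), 10⁴
(moment checks at 3-SE tolerance) and 40-trial × 200-replicate
meta-analysis simulations keep the full suite under ~15 s on one core.

## Shape classification

Averaging Rt within equal-width Rc bins (`effect_curve()`, 20 bins by
default) gives the mean curve, which `classify_shape()` assigns to one of
five canonical representations: a line through the origin, a line with a
threshold, and curvilinear shapes without, with a lower, or with both
diagonal crossings. A line is declared when the RMS residual of a weighted
linear fit, relative to the Rt range, is below `tol_linear = 0.02`; the
intercept is "zero" below `tol_zero = 0.005` risk units. These defaults
are loose enough for 200-subject binned curves and tight enough to
separate generated fixtures of each shape. Diagonal crossings are located
by sign changes of `rt − rc` along the sorted curve with linear
interpolation; a crossing in the bottom third of the observed Rc range
counts as a lower threshold, in the top third as an upper one. A crossing
confined to the top third alone has no label of its own in the
five-category scheme and is reported as plain curvilinear.

## Uncertainty and decisions

`npe_prediction_interval()` bootstraps subjects (resample with
replacement, recompute `NPE = Σ AB`; the models being deterministic per
subject, this resamples the population composition) and returns a seeded
percentile interval. `NPE` itself is conserved exactly: it equals the sum
of per-subject ABs to machine precision and doubles exactly when the
population is duplicated.

Decision rules:

* `natural_threshold_decision()` treats strictly above `s` (a patient
  exactly at the threshold gains nothing).
* `compare_treatments()` predicts AB per candidate therapy for one subject
  — all candidates share the disease model and must share the follow-up,
  otherwise ABs are not comparable and an error is raised — and recommends
  the argmax, with exact ties broken by label order and flagged.
* `allocate_budget()` treats greedily in decreasing AB while the budget
  lasts, never at AB ≤ 0 even under slack budget; under uniform unit cost
  greedy is provably optimal, which the tests confirm against exhaustive
  subset search on populations of up to 12. The AB of the last treated
  subject is the operational, externally imposed threshold.

When the effect model is curvilinear, the Rc-threshold rule and the
AB-threshold rule can disagree (AB peaks at intermediate Rc and declines
again). Both rules are provided and the discrepancy is left visible to the
analyst rather than resolved by fiat.

## Known limitations

* The naive Rt-on-Rc regression is biased with small trials; the package
  documents and demonstrates this instead of correcting it.
* The mechanistic chain is a minimal reconstruction honouring each named
  step and descriptor role; it is validated against internal oracles
  (closed form, ODE integration), not against an external reference
  implementation.
* One event per effect model: a disease expressed through several events
  needs as many effect models, and composite outcomes are out of scope.
* Multi-compartment PK, correlated descriptors, instant-hazard (time
  resolved) formulations and measurement-error-corrected regression are
  out of scope.
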