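---
title: "Methods: doubly robust estimation and two-way causal mediation for three-wave cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: doubly robust estimation and two-way causal mediation for three-wave cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drmediate)
```

## The problem this package addresses

In adolescent cohort studies, a baseline behavioural trait (here a
hyperactivity/inattention score at the first wave) may act on later
mental-health outcomes (depressive symptoms, anxiety, psychotic
experiences, diminished well-being at the third wave) partly through an
intermediate-wave addictive behaviour (problematic online gaming symptoms
at the second wave). Quantifying that pathway well requires three things at
once: a clear temporal order of exposure, mediator and outcome; thorough
confounder adjustment for all three pairwise relations; and an
exposure–mediator interaction in the outcome model, because the effect of
the behaviour plausibly differs by the level of the trait that predisposes
to it.

`drmediate` implements that analysis as a reusable, testable pipeline:

1. a **synthetic-cohort generator** with the statistical structure the
   analysis assumes, plus closed-form true effects for validation;
2. **scale scoring and dichotomization** for the five instruments
   involved;
3. **iterative random-forest imputation** of missing cells;
4. **per-SD linear association models** (three nested adjustment tiers)
   and a modified-Poisson risk-ratio sensitivity model;
5. a **doubly robust estimator** of the risk difference and risk ratio of
   the dichotomized mediator-wave behaviour on each dichotomized outcome,
   with percentile-bootstrap CIs, gender-interaction measures (RERI, RRR)
   and E-values;
6. **regression-based causal mediation** with exposure–mediator
   interaction: the two-way decomposition into pure direct and total
   indirect effects, the proportion mediated, delta-method CIs, and a
   Monte-Carlo counterfactual oracle that validates the closed forms.

## The synthetic cohort

The generator (`cohort_config()`, `generate_cohort()`) is first-class,
tested code, not a fixture. Covariates are drawn from fixed marginals
matched, where published, to the baseline table of the cohort the package
emulates: IQ normal with mean 110 and SD 14.9, BMI 17.9 (2.51), age 12.2
(0.28), 53.1% boys, three-level household income with the printed category
frequencies, binary loneliness, physical punishment, gender-nonconforming
behaviour and time-spent-gaming indicators at their printed prevalences,
1–5 relationship scales, and a right-skewed (gamma-based) problematic
internet use score with mean 3.94 and SD 4.16. The internet-use upper
bound of 33 is a simulator convention; the instrument's range is not
published.

Structural equations are linear-Gaussian on a latent scale:

* exposure `A* = a0 + b'C + e`, rounded to the 0–10 integer grid;
* mediator `M* = alpha0 + alpha1 A + c'C + e`, rounded to 0–9;
* outcome `Y* = theta0 + theta1 A + theta2 M + theta3 A*M + d'C +
  rho Y_w1 + e`, rounded/clipped to each instrument's grid (integers for
  the depression and anxiety scales, half points for psychotic
  experiences, steps of four for well-being).

Two design choices matter for validation. First, every downstream
equation consumes the **rounded** upstream score, so ordinary least
squares on the generated table is exactly specified in the observed
variables (rounding the response only adds noise with negligible
oscillatory bias when the residual SD is at least the grid step). Second,
rounding is half-up (`round_half_up()`), and intercepts are derived from
requested marginal means, so re-centering a scale is a one-argument
change.

Wave-1 outcome scores are generated from the same confounders (scaled
80%) plus independent noise, so adjusting for them is meaningful.

`true_effects()` returns the closed-form two-way decomposition implied by
the coefficients,

```
pde = (theta1 + theta3 * E[M | a0, cbar]) * (a1 - a0)
tie = (theta2 + theta3 * a1) * alpha1 * (a1 - a0)
te  = pde + tie   (exactly)
```

valid on the latent scale. Near the scale floors (the default
configuration reproduces the published marginals, with depressive-symptom
means around 4 on a 0–26 scale) clipping compresses fitted coefficients,
so these closed forms are only approximate for the observed data.
Estimator-validation simulations therefore use a *recovery configuration*
with mid-scale means (exposure mean 5, mediator mean 4.5, outcome means at
mid-range), where clipping is absent and the closed forms are exact for
the observed data; this is a property of validating the estimator where
its assumptions hold, not a statement about the default world. Real
symptom scales are right-skewed with floor effects; the generator's
truncated Gaussians do not reproduce that skew, so passing recovery tests
demonstrates estimator correctness, not robustness to floor-compressed
real data.

Missingness (`apply_missingness()`) is MCAR or MAR-on-observed; under MAR
the cell-missingness logit depends only on gender and the exposure score
(which must then stay observed), with the intercept calibrated by
root-finding so the marginal rate matches the configured per-variable
rate. Default rates follow the published baseline missingness table.

For validating the doubly robust estimator a separate benchmark world
(`simulate_dr_benchmark()`) is provided in which the binary group and
binary outcome follow *exact* logistic laws on two standard-normal
covariates, with true counterfactual risks computed by large Monte Carlo.
The cohort generator's binary outcomes arise by thresholding rounded
latent Gaussians, so no analyst-side GLM is exactly correct there and
"unbiasedness within Monte-Carlo error" is not a property any parametric
estimator can have on it; the benchmark makes the property testable.
Misspecification knobs add an omitted `0.6*(z1^2 - 1)` term to the
propensity law, the outcome law, or both — the standard construction for
demonstrating double robustness.

## Scoring and dichotomization

`scale_registry()` encodes the instruments: 5-item hyperactivity subscale
(0–10), 9-item gaming screen (0–9), 13-item depression scale (0–26),
14-item anxiety subset (0–28), 7-item psychotic-experience screener (0–7
in half points), and the 5-item well-being index (items 0–5, total
multiplied by four, 0–100). Missing items are never prorated; totals are
computed only from complete item sets, with item-level missingness
resolved upstream by imputation of totals.

Cut-offs (`cutoff_rules()`): gaming high group at ≥ 4 symptoms (low 0–3,
high 4–9); depression at a total ≥ 8; anxiety at a T-score of 65, i.e.
+1.5 reference SDs; psychotic experiences at ≥ 1 "yes, definitely" item;
diminished well-being at a total ≤ 50. Three conventions are package
decisions where the source conventions are unstated:

* **Well-being boundary side**: a score exactly 50 counts as diminished
  (`<=`), configurable to strict `<`.
* **Anxiety T reference**: computed from the analysis sample itself,
  gender-specific, at the outcome wave (no external norm table is
  assumed); an explicit reference can be supplied.
* **Psychotic-experience case from totals**: when item-level data are
  absent, a total ≥ 1 is used (a definite item contributes 1.0 on the
  half-point scale; two "maybe" responses also reach 1, so this is a
  slightly liberal proxy). Item-level data, when available, use the exact
  ≥ 1-definite-item rule.

"Incident" outcomes are operationalized as case status at wave 3 with the
wave-1 continuous score entered as a covariate, not by excluding baseline
cases.

## Imputation

`rf_impute()` implements the iterative forest scheme: mean/mode
initialization, variables visited in ascending missingness, each
incomplete variable regressed on all others with a forest (`ranger`, 100
trees by default) fit to its observed rows, missing cells replaced by
predictions, sweeps repeated until the difference statistic between
successive imputations first rises (the previous sweep is then returned)
or 10 sweeps. Observed cells are preserved exactly; continuous
imputations are clipped to the observed range; the whole procedure is
deterministic given the seed. A single imputation is performed upstream
of all analyses; the bootstrap for the doubly robust stage resamples the
*completed* table rather than re-imputing per replicate — a deliberate
runtime trade-off that slightly understates the imputation share of
uncertainty.

## Association models

Three nested adjustment tiers (`model_roster()`): unadjusted;
demographics (age, gender, BMI, IQ, income); plus the psychosocial block
(loneliness, physical punishment, three relationship scales, neighborhood
cohesion, gender nonconformity) and, for the gaming-to-outcome analysis,
the hyperactivity score and the analyzed outcome's baseline; the
exposure-to-gaming analysis instead adds the two baseline gaming proxies.
Coefficients are reported per 1 SD of the exposure; stratified fits reuse
the overall-sample SD so coefficients are comparable across strata.
The risk-ratio sensitivity model is log-link Poisson with HC0 sandwich
standard errors — without robust variance, Poisson CIs for binary
outcomes are invalid.

## Doubly robust estimation

`dr_estimate()` composes `fit_propensity()` (logistic propensity for the
high-gaming group, inverse probability weights `1/e` and `1/(1-e)`) with
a *weighted* canonical-link logistic outcome model including exposure and
covariates, then standardizes (g-formula): each subject's outcome
probability is predicted under exposure 1 and 0 and averaged over the
full sample. The combination is consistent if either the propensity or
the outcome model is correct; the package tests that property directly on
the benchmark world. Percentile-bootstrap CIs resample subjects and rerun
the entire pipeline per replicate (500–1000 replicates; failed replicates
are dropped and counted, more than 10% failures aborts). Weights are not
truncated by default; percentile truncation is available via
`truncate_weights`.

Gender heterogeneity (`reri_rrr()`) refits the weighted outcome model
with a gaming-by-gender product term, standardizes the four joint-category
risks against a common reference — (low gaming, boys) by default,
configurable — and reports `RERI = RR11 - RR10 - RR01 + 1` (additive
scale) and `RRR = RR11 / (RR10 * RR01)` (multiplicative scale) with
bootstrap CIs.

`e_value()` computes `RR + sqrt(RR*(RR-1))` after inverting ratios below
1; for a CI the bound closer to the null is used and the E-value is 1
when the interval crosses 1.

## Causal mediation with exposure–mediator interaction

`mediate_twoway()` fits two OLS models — mediator on exposure plus
covariates, outcome on exposure, mediator, their product and covariates —
and evaluates the two-way decomposition at the covariate sample means
(in linear models this equals averaging over the empirical covariate
distribution) for the contrast from the exposure mean to the mean plus
one SD. Both levels are treated as fixed constants; the delta method
propagates the two coefficient-covariance blocks (assumed independent,
standard for separately fitted models) through the analytic gradients of
`te`, `pde` and `tie`. With no interaction the indirect-effect SE reduces
exactly to the Sobel formula, which the tests verify. The identity
`te = pde + tie` holds to machine precision by construction. Mediator and
outcome are treated as continuous here (well-being reverse-scored so all
outcomes are oriented higher-worse), even though the doubly robust stage
dichotomizes them.

`mc_counterfactual_oracle()` is an independent check: it simulates the
mediator's Gaussian law under each exposure level (common residual per
draw, so `M(a1) = M(a0) + alpha1*(a1-a0)`) and averages the outcome-model
mean function over draws; for linear models the closed forms must agree
within Monte-Carlo error, and do.

The proportion mediated, `100 * tie / te`, is reported as a percentage
and flagged when `te` and `tie` have opposite signs or `te` is near zero,
where the ratio loses interpretability. Gender-stratified mediation
refits both models within stratum while keeping the overall-sample
contrast levels for comparability.

## Numerical choices and problem sizes

* Rounding to scale grids is half-up; configurations whose constant
  scores fall exactly on a grid tie (e.g. a mean of 0.75 on the half-point
  scale) are resolved by the floating-point sign of the noise, so
  degenerate (zero-noise) configurations should avoid tie points.
* Separation in the propensity model (fitted probabilities within 1e-8 of
  0/1) is signalled with the affected subject count; bootstrap replicates
  that fail are dropped and counted.
* Rank-deficient designs are rejected with the offending columns named,
  never silently aliased.
* Validation simulations use 100 cohorts of n = 3000 (matching the order
  of magnitude of the emulated cohort) with 500 bootstrap replicates for
  coverage checks, 60 cohorts of n = 2000 per misspecification scenario,
  and Monte-Carlo oracles of 1e5 draws; these sizes give Monte-Carlo
  standard errors comfortably below the effects being checked.
* Every stochastic stage takes an explicit integer seed; identical
  configurations yield byte-identical pipeline outputs (the run manifest
  records a deterministic FNV-1a hash of the configuration).

## Known limitations

* The generator emulates marginals and a linear mediated structure, not
  the joint covariate distribution, skewed symptom distributions, or
  attrition-as-a-process of a real cohort.
* Bootstrap CIs do not re-run imputation per replicate.
* The mediation stage is linear-continuous; odds-ratio-scale mediation
  for binary outcomes and three/four-way decompositions are out of scope.
* E-values quantify robustness to unmeasured confounding only on the
  risk-ratio scale and do not address measurement error.
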