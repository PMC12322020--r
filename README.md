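# drmediate

Doubly robust effect estimation and causal mediation analysis for
three-wave adolescent cohort studies, built around one scientific
question: how much of the effect of a baseline behavioural trait
(hyperactivity/inattention at wave 1) on later mental-health outcomes
(depressive symptoms, anxiety, psychotic experiences and diminished
well-being at wave 3) flows through an intermediate addictive behaviour
(problematic online gaming at wave 2)?

The package is for epidemiologists and biostatisticians who want that
analysis as tested, reusable code: every stage — cohort simulation, scale
scoring, imputation, estimation — is a documented function with
property-based tests, and a synthetic-cohort generator with closed-form
true effects stands in for restricted cohort data so the whole pipeline
is verifiable without any download.

## What it computes

**Doubly robust risk difference and risk ratio.** For the dichotomized
mediator-wave behaviour (high gaming, ≥ 4 of 9 symptoms) and each
dichotomized outcome, a logistic propensity model yields inverse
probability weights `1/e(C)` (exposed) and `1/(1-e(C))` (unexposed); a
*weighted* canonical-link outcome model is then standardized by the
g-formula,

    risk_a = mean over subjects of P(Y = 1 | A = a, C_i),
    RD = risk_1 - risk_0,   RR = risk_1 / risk_0,

which is consistent if either model is correctly specified. CIs are
percentile bootstrap over subjects. Gender heterogeneity is summarized by
the relative excess risk due to interaction and the ratio of risk ratios,

    RERI = RR11 - RR10 - RR01 + 1,   RRR = RR11 / (RR10 * RR01),

and robustness to unmeasured confounding by the E-value,
`RR + sqrt(RR (RR - 1))`.

**Two-way causal mediation with exposure–mediator interaction.** From a
mediator regression `E[M] = alpha0 + alpha1 A + alpha2'C` and an outcome
regression `E[Y] = theta0 + theta1 A + theta2 M + theta3 A M + theta4'C`,
the total effect of raising the exposure from `a0` (the mean) to `a1`
(mean + 1 SD) decomposes as

    PDE = (theta1 + theta3 E[M | a0, cbar]) (a1 - a0)
    TIE = (theta2 + theta3 a1) alpha1 (a1 - a0)
    TE  = PDE + TIE,    proportion mediated = TIE / TE,

with delta-method CIs and an independent Monte-Carlo counterfactual
oracle validating the closed forms.

Supporting stages: per-SD linear association models in three nested
adjustment tiers, modified-Poisson (sandwich-variance) risk ratios, scale
scoring/dichotomization for the five instruments, iterative random-forest
imputation, and an end-to-end `run_pipeline()` with byte-reproducible
outputs.

## Worked example

```r
library(drmediate)

cfg <- cohort_config(n_subjects = 2000, seed = 7)   # default cohort marginals
tab <- generate_cohort(cfg)
cases <- dichotomize_outcome(
  data.frame(smfq = tab$smfq_w3, anxiety = tab$anxiety_w3,
             apss = tab$apss_w3, who5 = tab$who5_w3),
  gender = tab$male)
tab$depression_case <- as.numeric(cases$depression_case)
tab$gaming_high <- as.numeric(dichotomize_gaming(tab$gaming) == "high")

covs <- model_roster(3, "outcome", baseline_outcome = "smfq_w1")
fit <- dr_estimate(tab, "depression_case", "gaming_high", covs,
                   n_boot = 500, seed = 42)
fit
#> Doubly robust estimate: depression_case ~ gaming_high (n = 2000)
#>   risk1 0.3734  risk0 0.1902
#>   RD 0.1832 (95% CI 0.1199 to 0.2439)
#>   RR 1.963 (95% CI 1.634 to 2.341)  [500 bootstrap, 0 dropped]

e_value(fit$rr, fit$ci_rr[1], fit$ci_rr[2])
#> E-value (point): 3.339   (CI bound): 2.652

med <- mediate_twoway(tab, "smfq_w3", "adhd", "gaming",
                      model_roster(3, "mediation",
                                   baseline_outcome = "smfq_w1"))
med
#> Causal mediation (two-way decomposition): adhd -> gaming -> smfq_w3
#>   n = 2000, contrast 3.630 -> 5.457
#>   TE     0.4587 (95% CI   0.3151 to   0.6023)
#>   PDE    0.3181 (95% CI   0.1778 to   0.4585)
#>   TIE    0.1406 (95% CI   0.0932 to   0.1879)
#>   proportion mediated: 30.6%
```

Reading the output: in this simulated cohort the high-gaming group has an
18.3 percentage-point higher adjusted risk of crossing the depression
cut-off (a 1.96-fold relative risk); an unmeasured confounder would need
risk-ratio associations of 3.3 with both exposure and outcome to explain
that away. A one-SD increase in the hyperactivity score raises the wave-3
depressive-symptom total by 0.46 points, of which 0.14 points (31%) flow
through the gaming pathway — close to this configuration's closed-form
truth, which `true_effects(cfg, ...)` returns.

The full pipeline (generate, blank, impute, score, all analyses, TSV/JSON
outputs plus manifest) runs as

```r
run_pipeline(pipeline_config(generation = cfg), out_dir = "results/run1")
```

## Package layout

- `R/synthetic-cohort.R` — generator, missingness, closed-form truths,
  DR benchmark world
- `R/measures.R` — scale registry, scoring, cut-offs, Cronbach's alpha
- `R/imputation.R` — iterative random-forest imputation
- `R/association.R` — per-SD linear models, modified Poisson RR
- `R/doubly-robust.R` — propensity/IPW, g-formula DR, bootstrap, RERI/RRR,
  E-values
- `R/mediation.R` — two-way decomposition, delta method, MC oracle
- `R/pipeline.R` — end-to-end orchestration with YAML config
- `vignettes/drmediate-methods.Rmd` — the methods vignette (model,
  assumptions, design choices, limitations)
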