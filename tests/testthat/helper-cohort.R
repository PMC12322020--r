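# shared fixtures built in code

# a small complete cohort with case indicators and the dichotomized
# mediator attached, as produced by the scoring stage
scored_cohort <- function(n = 2000, seed = 42, ...) {
  cfg <- cohort_config(n_subjects = n, seed = seed, ...)
  tab <- generate_cohort(cfg)
  cases <- dichotomize_outcome(
    data.frame(smfq = tab$smfq_w3, anxiety = tab$anxiety_w3,
               apss = tab$apss_w3, who5 = tab$who5_w3),
    gender = tab$male)
  for (v in names(cases)) tab[[v]] <- as.numeric(cases[[v]])
  tab$gaming_high <- as.numeric(tab$gaming >= 4)
  tab$who5_w3_rev <- reverse_wellbeing(tab$who5_w3)
  attr(tab, "config") <- cfg
  tab
}

# configuration used for estimator-validation simulations: outcome scales
# centred mid-range so boundary clipping is absent and the latent-scale
# closed-form true effects are exact for the observed data
recovery_config <- function(n = 3000, seed = 1, ...) {
  cohort_config(
    n_subjects = n, seed = seed,
    exposure_mean = 5, mediator_mean = 4.5,
    outcome_means = c(smfq = 13, anxiety = 14, apss = 3.5, who5 = 50),
    baseline_means = c(smfq = 13, anxiety = 14, apss = 3.5, who5 = 50),
    ...)
}
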