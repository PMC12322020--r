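# hand-built model objects for closed-form checks
toy_models <- function(alpha0 = 2, alpha1 = 0.5, theta1 = 1, theta2 = 2,
                       theta3 = 0.1, sigma = 1, vm = NULL, vo = NULL) {
  if (is.null(vm)) vm <- diag(0, 2)
  if (is.null(vo)) vo <- diag(0, 4)
  mm <- structure(list(
    coef = c("(Intercept)" = alpha0, a = alpha1),
    vcov = vm, sigma = sigma, exposure = "a",
    covariates = character(0), n = 100L), class = "mediator_model")
  om <- structure(list(
    coef = c("(Intercept)" = 0, a = theta1, m = theta2, `a:m` = theta3),
    vcov = vo, exposure = "a", mediator = "m",
    interaction = "a:m", covariates = character(0), n = 100L),
    class = "outcome_model")
  list(mm = mm, om = om)
}

test_that("the two-way decomposition matches the hand-evaluated example", {
  tm <- toy_models()  # alpha0 + alpha2'cbar = 2, alpha1 = 0.5
  dec <- two_way_decompose(tm$mm, tm$om, a0 = 0, a1 = 1)
  expect_equal(dec$pde, 1.2)
  expect_equal(dec$tie, 1.05)
  expect_equal(dec$te, 2.25)
  expect_equal(dec$pm, 1.05 / 2.25)
})

test_that("interaction-free and mediation-free limits hold", {
  tm <- toy_models(theta3 = 0)
  dec <- two_way_decompose(tm$mm, tm$om, a0 = 0, a1 = 2)
  expect_equal(dec$tie, 2 * 0.5 * 2)        # theta2 * alpha1 * delta
  expect_equal(dec$pde, 1 * 2)              # theta1 * delta exactly
  tm0 <- toy_models(alpha1 = 0)
  dec0 <- two_way_decompose(tm0$mm, tm0$om, a0 = 0, a1 = 2)
  expect_equal(dec0$tie, 0)
  expect_equal(dec0$pm, 0)
  expect_error(two_way_decompose(tm$mm, tm$om, a0 = 1, a1 = 1), "a1")
})

test_that("te equals pde + tie to machine precision across random inputs", {
  set.seed(31)
  for (i in 1:25) {
    tm <- toy_models(alpha0 = rnorm(1), alpha1 = rnorm(1),
                     theta1 = rnorm(1), theta2 = rnorm(1),
                     theta3 = rnorm(1))
    a0 <- rnorm(1); a1 <- a0 + abs(rnorm(1)) + 0.1
    dec <- two_way_decompose(tm$mm, tm$om, a0, a1)
    expect_identical(dec$te, dec$pde + dec$tie)
  }
})

test_that("fitted coefficients recover the generator truth at n = 20000", {
  cfg <- recovery_config(n = 20000, seed = 81)
  tab <- generate_cohort(cfg)
  covs <- model_roster(3, "mediation", baseline_outcome = "smfq_w1")
  fits <- fit_mediation_models(tab, "smfq_w3", "adhd", "gaming", covs)
  mm <- fits$mediator_model; om <- fits$outcome_model
  expect_lt(abs(mm$coef[["adhd"]] - cfg$alpha1),
            3 * sqrt(mm$vcov["adhd", "adhd"]))
  expect_lt(abs(om$coef[["gaming"]] - cfg$theta2[["smfq"]]),
            3 * sqrt(om$vcov["gaming", "gaming"]))
  expect_lt(abs(om$coef[["adhd:gaming"]] - cfg$theta3[["smfq"]]),
            3 * sqrt(om$vcov["adhd:gaming", "adhd:gaming"]))

  # configured zero interaction is recovered as null
  cfg0 <- recovery_config(n = 20000, seed = 82, theta3 = 0)
  tab0 <- generate_cohort(cfg0)
  f0 <- fit_mediation_models(tab0, "smfq_w3", "adhd", "gaming", covs)
  expect_lt(abs(f0$outcome_model$coef[["adhd:gaming"]]),
            3 * sqrt(f0$outcome_model$vcov["adhd:gaming", "adhd:gaming"]))

  # duplicated mediator among covariates is rejected
  tab$gaming2 <- tab$gaming
  expect_error(
    fit_mediation_models(tab, "smfq_w3", "adhd", "gaming",
                         c(covs, "gaming2")), "gaming2")
})

test_that("zero coefficient variance collapses the delta-method CIs to points", {
  tm <- toy_models()
  ci <- delta_method_ci(tm$mm, tm$om, a0 = 0, a1 = 1)
  expect_equal(ci$se, rep(0, 3))
  expect_equal(ci$ci_low, ci$estimate)
  expect_equal(ci$ci_high, ci$estimate)
})

test_that("without interaction the indirect-effect SE is the Sobel formula", {
  va <- 0.04; vt2 <- 0.09
  tm <- toy_models(theta3 = 0,
                   vm = diag(c(0, va)),
                   vo = diag(c(0, 0, vt2, 0)))
  ci <- delta_method_ci(tm$mm, tm$om, a0 = 0, a1 = 1)
  sobel <- sqrt(2^2 * va + 0.5^2 * vt2)  # theta2 = 2, alpha1 = 0.5
  expect_equal(ci$se[ci$effect == "tie"], sobel, tolerance = 1e-10)
})

test_that("delta-method CIs agree with a bootstrap on one synthetic cohort", {
  cfg <- recovery_config(n = 3000, seed = 83)
  tab <- generate_cohort(cfg)
  covs <- model_roster(2)
  fit <- mediate_twoway(tab, "smfq_w3", "adhd", "gaming", covs)
  nb <- 400
  set.seed(9)
  draws <- matrix(NA_real_, nb, 3)
  for (b in seq_len(nb)) {
    idx <- sample.int(nrow(tab), nrow(tab), replace = TRUE)
    fb <- mediate_twoway(tab[idx, ], "smfq_w3", "adhd", "gaming", covs,
                         a0 = fit$a0, a1 = fit$a1)
    draws[b, ] <- coef(fb)
  }
  ci_boot <- apply(draws, 2, quantile, c(0.025, 0.975))
  delta <- confint(fit)
  for (j in 1:3) {
    w_d <- delta[j, 2] - delta[j, 1]
    w_b <- ci_boot[2, j] - ci_boot[1, j]
    expect_lt(abs(w_d - w_b) / w_b, 0.2)
  }
})

test_that("the Monte-Carlo counterfactual oracle matches the closed forms", {
  set.seed(17)
  for (i in 1:10) {
    tm <- toy_models(alpha0 = rnorm(1), alpha1 = rnorm(1),
                     theta1 = rnorm(1), theta2 = rnorm(1),
                     theta3 = rnorm(1), sigma = runif(1, 0.5, 2))
    a0 <- rnorm(1); a1 <- a0 + 1
    dec <- two_way_decompose(tm$mm, tm$om, a0, a1)
    or <- mc_counterfactual_oracle(tm$mm, tm$om, NULL, a0, a1,
                                   n_draws = 50000, seed = i)
    expect_lt(abs(or$nde - dec$pde), 3 * or$se_nde + 1e-12)
    expect_lt(abs(or$nie - dec$tie), 3 * or$se_nie + 1e-12)
  }
  # vanishing mediator noise makes the oracle exact, and seeds reproduce
  tm <- toy_models(sigma = 1e-12)
  dec <- two_way_decompose(tm$mm, tm$om, 0, 1)
  or <- mc_counterfactual_oracle(tm$mm, tm$om, NULL, 0, 1,
                                 n_draws = 2000, seed = 3)
  expect_equal(or$nde, dec$pde, tolerance = 1e-8)
  expect_equal(or$nie, dec$tie, tolerance = 1e-8)
  or2 <- mc_counterfactual_oracle(tm$mm, tm$om, NULL, 0, 1,
                                  n_draws = 2000, seed = 3)
  expect_identical(or, or2)
  expect_error(mc_counterfactual_oracle(tm$mm, tm$om, NULL, 0, 1,
                                        n_draws = 10), "n_draws")
})

test_that("proportion mediated reports percentages and flags pathologies", {
  expect_equal(proportion_mediated(0.26, 0.08), 100 * 0.08 / 0.26)
  expect_equal(proportion_mediated(2, 0), 0)
  expect_equal(proportion_mediated(2, 2), 100)
  expect_error(proportion_mediated(0, 1), "zero")
  expect_warning(proportion_mediated(1, -0.2), "opposite")
  tm <- toy_models(alpha1 = 0.5, theta1 = -1.3, theta2 = 2, theta3 = 0.1)
  dec <- suppressWarnings(two_way_decompose(tm$mm, tm$om, 0, 1))
  expect_lt(dec$te * dec$tie, 0)  # opposite signs by construction
  expect_true(attr(dec, "flagged"))
})

test_that("decomposition is invariant to covariate recentering with consistent cbar", {
  cfg <- recovery_config(n = 4000, seed = 85)
  tab <- generate_cohort(cfg)
  covs <- c("age", "iq", "loneliness")
  f1 <- mediate_twoway(tab, "smfq_w3", "adhd", "gaming", covs)
  tab2 <- tab
  tab2$age <- tab2$age - 12
  tab2$iq <- tab2$iq - 100
  f2 <- mediate_twoway(tab2, "smfq_w3", "adhd", "gaming", covs)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("mediation fit methods expose the decomposition coherently", {
  tab <- scored_cohort(n = 1200, seed = 86)
  fit <- mediate_twoway(tab, "smfq_w3", "adhd", "gaming",
                        model_roster(2))
  expect_s3_class(fit, "mediation_fit")
  cf <- coef(fit)
  expect_equal(unname(cf["te"]), unname(cf["pde"] + cf["tie"]))
  ci <- confint(fit)
  expect_equal(rownames(ci), c("te", "pde", "tie"))
  expect_true(all(ci[, 1] <= cf & cf <= ci[, 2]))
  s <- summary(fit)
  expect_equal(attr(s, "pm_percent"), fit$pm_percent)
  expect_output(print(fit), "proportion mediated")
})
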