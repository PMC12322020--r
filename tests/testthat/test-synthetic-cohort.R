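test_that("generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_subjects = 300, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_subjects = 300, seed = 8)
  expect_false(identical(generate_cohort(cfg)$adhd,
                         generate_cohort(cfg2)$adhd))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(noise_sd_mediator = 0), "noise_sd_mediator")
  expect_error(cohort_config(noise_sd_mediator = -1), "noise_sd_mediator")
  expect_error(cohort_config(missing_rates = c(bmi = 1.2)), "missing_rates")
  expect_error(cohort_config(missing_mechanism = "MNAR"))
  expect_error(cohort_config(conf_to_mediator = c(nope = 1)),
               "conf_to_mediator")
})

test_that("zero coefficients and near-zero noise give constant scores", {
  cfg <- cohort_config(
    n_subjects = 200, seed = 3, alpha1 = 0,
    theta1 = 0, theta2 = 0, theta3 = 0, carryover = 0,
    conf_to_exposure = c(age = 0), conf_to_mediator = c(age = 0),
    conf_to_outcome = list(smfq = c(age = 0), anxiety = c(age = 0),
                           apss = c(age = 0), who5 = c(age = 0)),
    noise_sd_exposure = 1e-9, noise_sd_mediator = 1e-9,
    noise_sd_outcome = 1e-9,
    outcome_means = c(apss = 0.8))  # off the 0.5-grid tie point
  tab <- generate_cohort(cfg)
  expect_equal(unique(tab$gaming), round(cfg$mediator_mean))
  expect_equal(unique(tab$smfq_w3), round(cfg$outcome_means[["smfq"]]))
  expect_equal(unique(tab$apss_w3),
               round_half_up(cfg$outcome_means[["apss"]], 0.5))
})

test_that("all scores stay inside their scale ranges", {
  tab <- generate_cohort(cohort_config(n_subjects = 4000, seed = 5))
  expect_true(all(tab$adhd >= 0 & tab$adhd <= 10))
  expect_true(all(tab$gaming >= 0 & tab$gaming <= 9))
  expect_true(all(tab$smfq_w3 >= 0 & tab$smfq_w3 <= 26))
  expect_true(all(tab$anxiety_w3 >= 0 & tab$anxiety_w3 <= 28))
  expect_true(all(tab$apss_w3 >= 0 & tab$apss_w3 <= 7))
  expect_true(all(tab$apss_w3 %% 0.5 == 0))
  expect_true(all(tab$who5_w3 >= 0 & tab$who5_w3 <= 100))
  expect_true(all(tab$who5_w3 %% 4 == 0))
  expect_true(all(tab$rel_mother %in% 1:5))
  expect_true(all(tab$income %in% 1:3))
  expect_false(any(duplicated(tab$subject_id)))
})

test_that("covariate marginals match configured targets at n = 10^4", {
  cfg <- cohort_config(n_subjects = 10000, seed = 21)
  tab <- generate_cohort(cfg)
  n <- nrow(tab)
  # lightly clipped / rounded marginals: mean within 3 MC SEs of target
  for (v in c("age", "bmi", "iq")) {
    m <- cfg$covariate_marginals[[v]]
    expect_lt(abs(mean(tab[[v]]) - m$mean), 3 * m$sd / sqrt(n))
  }
  for (v in c("male", "loneliness", "time_gaming")) {
    p <- cfg$covariate_marginals[[v]]$mean
    expect_lt(abs(mean(tab[[v]]) - p), 3 * sqrt(p * (1 - p) / n))
  }
  expect_lt(abs(sd(tab$iq) - 14.9), 0.5)
})

test_that("the configured exposure-mediator slope is recovered by OLS", {
  cfg <- recovery_config(n = 20000, seed = 13, alpha1 = 0.5)
  tab <- generate_cohort(cfg)
  fit <- lm(gaming ~ adhd + male + time_gaming + prob_internet +
              loneliness + iq + rel_friends, data = tab)
  se <- sqrt(vcov(fit)["adhd", "adhd"])
  expect_lt(abs(coef(fit)[["adhd"]] - 0.5), 3 * se)
})

test_that("closed-form effects satisfy the hand-evaluated example and the identity", {
  # theta1=1, theta2=2, theta3=0.1, alpha1=0.5, E[M|a0]=3 at a0=0, a1=1
  cfg <- cohort_config(alpha1 = 0.5, theta1 = 1, theta2 = 2, theta3 = 0.1)
  cbar <- 0 * cfg$cov_means
  cfg$alpha0 <- 3  # E[M | a0=0, cbar=0] = alpha0
  te <- true_effects(cfg, a0 = 0, a1 = 1, cbar = cbar, outcome = "smfq")
  expect_equal(te$pde, 1.3)
  expect_equal(te$tie, 1.05)
  expect_equal(te$te, 2.35)

  # product-of-coefficients limit and alpha1 = 0 limit
  cfg2 <- cohort_config(alpha1 = 0.5, theta2 = 2, theta3 = 0)
  te2 <- true_effects(cfg2, a0 = 1, a1 = 3, outcome = "smfq")
  expect_equal(te2$tie, 2 * 0.5 * 2)
  cfg3 <- cohort_config(alpha1 = 0)
  te3 <- true_effects(cfg3, a0 = 1, a1 = 3, outcome = "anxiety")
  expect_equal(te3$tie, 0)
  expect_equal(te3$te, te3$pde)

  # identity holds exactly across random configurations
  set.seed(9)
  for (i in 1:20) {
    cfg4 <- cohort_config(alpha1 = rnorm(1), theta1 = rnorm(1),
                          theta2 = rnorm(1), theta3 = rnorm(1))
    tt <- true_effects(cfg4, a0 = rnorm(1), a1 = rnorm(1) + 5,
                       outcome = sample(c("smfq", "anxiety", "apss",
                                          "who5"), 1))
    expect_identical(tt$te, tt$pde + tt$tie)
  }
})

test_that("missingness rates are honoured and degenerate rates handled", {
  cfg <- cohort_config(n_subjects = 10000, seed = 2,
                       missing_rates = c(bmi = 0.2, iq = 0))
  tab <- generate_cohort(cfg)
  out <- apply_missingness(tab, cfg)
  expect_false(anyNA(out$iq))
  # binomial 99% interval at n = 10^4
  expect_gt(mean(is.na(out$bmi)), 0.18)
  expect_lt(mean(is.na(out$bmi)), 0.22)

  cfg0 <- cohort_config(n_subjects = 500, seed = 2,
                        missing_rates = c(bmi = 0))
  tab0 <- generate_cohort(cfg0)
  expect_identical(apply_missingness(tab0, cfg0), tab0)

  cfg1 <- cohort_config(n_subjects = 200, seed = 2,
                        missing_rates = c(bmi = 1))
  tab1 <- generate_cohort(cfg1)
  expect_true(all(is.na(apply_missingness(tab1, cfg1)$bmi)))
})

test_that("MAR missingness depends on gender and exposure but hits its rate", {
  cfg <- cohort_config(n_subjects = 20000, seed = 17,
                       missing_rates = c(smfq_w3 = 0.25),
                       missing_mechanism = "MAR")
  tab <- generate_cohort(cfg)
  out <- apply_missingness(tab, cfg)
  miss <- is.na(out$smfq_w3)
  expect_lt(abs(mean(miss) - 0.25), 0.02)
  # boys lose more cells than girls by construction
  expect_gt(mean(miss[tab$male == 1]), mean(miss[tab$male == 0]))
  # gender and exposure themselves must stay observed under MAR
  cfg_bad <- cohort_config(n_subjects = 100,
                           missing_rates = c(adhd = 0.1),
                           missing_mechanism = "MAR")
  tab_bad <- generate_cohort(cfg_bad)
  expect_error(apply_missingness(tab_bad, cfg_bad), "adhd")
})

test_that("cohort CSV round-trips with empty cells for missing values", {
  cfg <- cohort_config(n_subjects = 120, seed = 30)
  tab <- apply_missingness(generate_cohort(cfg), cfg)
  path <- tempfile(fileext = ".csv")
  write_cohort(tab, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_cohort(path)
  expect_equal(back$gaming, tab$gaming)
  expect_equal(which(is.na(back$bmi)), which(is.na(tab$bmi)))
  unlink(c(path, paste0(path, ".json")))
})

test_that("the benchmark world's truth is consistent with its crude margins", {
  bm <- simulate_dr_benchmark(50000, seed = 4, n_truth = 2e5)
  expect_true(all(bm$data$case %in% 0:1))
  expect_gt(bm$truth$rr, 1)      # positive group effect by construction
  expect_equal(bm$truth$rd, bm$truth$risk1 - bm$truth$risk0)
  # confounding is positive here, so the crude RD overstates the truth
  crude <- mean(bm$data$case[bm$data$group == 1]) -
    mean(bm$data$case[bm$data$group == 0])
  expect_gt(crude, bm$truth$rd)
})
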