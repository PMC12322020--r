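test_that("saturated propensity model reproduces stratum exposure fractions", {
  set.seed(1)
  n <- 400
  z <- rep(c(0, 1), each = n / 2)
  g <- as.numeric(runif(n) < ifelse(z == 1, 0.7, 0.3))
  df <- data.frame(z = z, g = g)
  pw <- fit_propensity(df, "g", "z")
  for (zv in 0:1) {
    frac <- mean(g[z == zv])
    expect_equal(unique(round(pw$propensity[z == zv], 10)), round(frac, 10))
  }
  # constant-only model: weight of exposed subjects is 1 / prevalence
  pw0 <- fit_propensity(df, "g")
  expect_equal(unique(round(pw0$weight[g == 1], 10)),
               round(1 / mean(g), 10))
  # mean inverse-probability weight is about 2 overall
  expect_lt(abs(mean(pw$weight) - 2), 0.05)
})

test_that("propensities approach the marginal prevalence when covariates are irrelevant", {
  set.seed(2)
  n <- 20000
  df <- data.frame(z = rnorm(n), g = as.numeric(runif(n) < 0.3))
  pw <- fit_propensity(df, "g", "z")
  expect_lt(max(abs(pw$propensity - mean(df$g))), 0.05)
})

test_that("standardization collapses to the crude 2x2 estimate without confounding", {
  set.seed(3)
  n <- 2000
  z <- rep(0:1, each = n / 2)          # covariate independent of exposure
  g <- rep(rep(0:1, each = n / 4), 2)  # balanced within z
  p <- 0.1 + 0.15 * g + 0.1 * z
  y <- as.numeric(runif(n) < p)
  df <- data.frame(z = z, g = g, y = y)
  fit <- dr_standardize(df, "y", "g", covariates = "z")
  crude <- mean(y[g == 1]) - mean(y[g == 0])
  expect_equal(fit$rd, crude, tolerance = 1e-10)
})

test_that("uniform weights reduce the DR fit to plain g-formula standardization", {
  tab <- scored_cohort(n = 1500, seed = 18)
  covs <- c("age", "male", "bmi", "iq")
  plain <- dr_standardize(tab, "depression_case", "gaming_high",
                          covariates = covs, weights = NULL)
  unif <- dr_standardize(tab, "depression_case", "gaming_high",
                         covariates = covs, weights = rep(1, nrow(tab)))
  expect_identical(plain$rd, unif$rd)
  expect_identical(plain$rr, unif$rr)
})

test_that("a never-occurring outcome is degenerate and signalled", {
  tab <- scored_cohort(n = 300, seed = 19)
  tab$never <- 0
  expect_warning(
    fit <- dr_standardize(tab, "never", "gaming_high", covariates = "male"),
    "undefined")
  expect_equal(fit$rd, 0)
  expect_true(is.na(fit$rr))
  tab$g1 <- 1
  expect_error(dr_standardize(tab, "depression_case", "g1"), "arm")
})

test_that("the DR estimate recovers the benchmark truth", {
  bm <- simulate_dr_benchmark(20000, seed = 61, n_truth = 5e5)
  fit <- dr_estimate(bm$data, "case", "group", c("z1", "z2"), n_boot = 0)
  # 3 Monte-Carlo SEs on a binomial risk scale at n = 20000
  mc_se <- sqrt(2 * 0.25 / 20000)
  expect_lt(abs(fit$rd - bm$truth$rd), 3 * mc_se)
  expect_lt(abs(fit$rr - bm$truth$rr), 0.15)
})

test_that("bootstrap CIs are deterministic given the seed and cover degenerate constants", {
  bm <- simulate_dr_benchmark(800, seed = 62)
  f1 <- dr_estimate(bm$data, "case", "group", c("z1", "z2"),
                    n_boot = 100, seed = 5)
  f2 <- dr_estimate(bm$data, "case", "group", c("z1", "z2"),
                    n_boot = 100, seed = 5)
  expect_identical(f1$ci_rd, f2$ci_rd)
  expect_identical(f1$ci_rr, f2$ci_rr)
  expect_lte(f1$ci_rd[1], f1$rd + 0.05)
  expect_gte(f1$ci_rd[2], f1$rd - 0.05)
})

test_that("joint-category RRs, RERI and RRR match hand-computed values", {
  # build a 2x2x2 world with exact cell risks giving rr10=1.5, rr01=1.2,
  # rr11=2.0 against the (0,0) reference risk 0.2
  cells <- expand.grid(g = 0:1, s = 0:1)
  risks <- c(0.2, 0.3, 0.24, 0.4)  # (0,0) (1,0) (0,1) (1,1)
  per_cell <- 500
  df <- do.call(rbind, lapply(seq_len(4), function(i) {
    k <- round(per_cell * risks[i])
    data.frame(g = cells$g[i], s = cells$s[i],
               y = rep(c(1, 0), c(k, per_cell - k)))
  }))
  ir <- reri_rrr(df, "y", "g", "s", reference_stratum = 0,
                 propensity_covariates = NULL, n_boot = 0)
  expect_equal(ir$rr10, 1.5, tolerance = 1e-8)
  expect_equal(ir$rr01, 1.2, tolerance = 1e-8)
  expect_equal(ir$rr11, 2.0, tolerance = 1e-8)
  expect_equal(ir$reri, 0.3, tolerance = 1e-8)
  expect_equal(ir$rrr, 2 / 1.8, tolerance = 1e-8)
})

test_that("RERI and RRR sit at their nulls for null and multiplicative worlds", {
  cells <- expand.grid(g = 0:1, s = 0:1)
  build <- function(risks, per_cell = 400) {
    do.call(rbind, lapply(seq_len(4), function(i) {
      k <- round(per_cell * risks[i])
      data.frame(g = cells$g[i], s = cells$s[i],
                 y = rep(c(1, 0), c(k, per_cell - k)))
    }))
  }
  ir0 <- reri_rrr(build(rep(0.25, 4)), "y", "g", "s",
                  reference_stratum = 0, propensity_covariates = NULL,
                  n_boot = 0)
  expect_equal(ir0$reri, 0, tolerance = 1e-8)
  expect_equal(ir0$rrr, 1, tolerance = 1e-8)
  # rr11 = rr10 * rr01 exactly => RRR = 1
  irm <- reri_rrr(build(c(0.2, 0.3, 0.24, 0.36)), "y", "g", "s",
                  reference_stratum = 0, propensity_covariates = NULL,
                  n_boot = 0)
  expect_equal(irm$rrr, 1, tolerance = 1e-8)
  # empty joint category is rejected
  df <- build(rep(0.25, 4))
  expect_error(
    reri_rrr(df[!(df$g == 1 & df$s == 1), ], "y", "g", "s",
             reference_stratum = 0, propensity_covariates = NULL,
             n_boot = 0), "empty")
})

test_that("E-values follow the closed form and its properties", {
  expect_equal(e_value(1)$evalue_point, 1)
  expect_equal(e_value(0.5)$evalue_point, 2 + sqrt(2), tolerance = 1e-10)
  expect_equal(e_value(4)$evalue_point, 4 + sqrt(12), tolerance = 1e-10)
  # monotone in rr >= 1 and always >= rr
  rrs <- seq(1, 5, by = 0.25)
  evs <- vapply(rrs, function(r) e_value(r)$evalue_point, numeric(1))
  expect_true(all(diff(evs) > 0))
  expect_true(all(evs >= rrs))
  # CI handling: bound closer to the null; 1 when the CI crosses 1
  expect_equal(e_value(1.62, 1.25, 2.05)$evalue_ci,
               1.25 + sqrt(1.25 * 0.25))
  expect_equal(e_value(1.62, 0.95, 2.05)$evalue_ci, 1)
  expect_equal(e_value(0.5, 0.3, 0.8)$evalue_ci,
               1.25 + sqrt(1.25 * 0.25))
  expect_error(e_value(0), "positive")
})
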