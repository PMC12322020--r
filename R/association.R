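new_effect_estimate <- function(point, se, ci_low, ci_high, scale, model,
                                stratum = "overall", n = NA_integer_,
                                p = NA_real_) {
  structure(list(point = point, se = se, ci_low = ci_low, ci_high = ci_high,
                 scale = scale, model = model, stratum = stratum,
                 n = n, p = p),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  lab <- switch(x$scale, beta_per_sd = "beta (per 1 SD)", beta = "beta",
                RD = "risk difference", RR = "risk ratio", x$scale)
  cat(sprintf("%s [%s, %s]: %.4g (95%% CI %.4g to %.4g), SE %.3g, p %.3g, n %d\n",
              lab, x$model, x$stratum, x$point, x$ci_low, x$ci_high,
              x$se, x$p, x$n))
  invisible(x)
}

check_design_rank <- function(fit) {
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  invisible(fit)
}

#' Covariate rosters for the three model tiers
#'
#' Tier 1 is unadjusted. Tier 2 adds age, gender, body mass index, IQ and
#' household income. Tier 3 adds loneliness, physical punishment,
#' relationships with mother, father and friends, neighborhood cohesion
#' and gender nonconformity, and then differs by analysis: the
#' gaming-to-outcome analysis further adjusts for the hyperactivity
#' exposure score and the analyzed outcome's baseline score; the
#' exposure-to-gaming analysis instead adds baseline time spent gaming and
#' problematic internet use; the mediation roster adds both gaming proxies
#' and the analyzed outcome's baseline score.
#'
#' @param tier 1, 2 or 3.
#' @param analysis `"outcome"`, `"exposure_mediator"` or `"mediation"`.
#' @param baseline_outcome wave-1 column name of the analyzed outcome
#'   (e.g. `"smfq_w1"`), required at tier 3 for the outcome and mediation
#'   rosters.
#' @return character vector of covariate column names (empty at tier 1).
#' @export
model_roster <- function(tier,
                         analysis = c("outcome", "exposure_mediator",
                                      "mediation"),
                         baseline_outcome = NULL) {
  analysis <- match.arg(analysis)
  if (!tier %in% 1:3) stop_field("tier", "must be 1, 2 or 3")
  if (tier == 1) return(character(0))
  t2 <- c("age", "male", "bmi", "iq", "income")
  if (tier == 2) return(t2)
  psycho <- c("loneliness", "phys_punish", "rel_mother", "rel_father",
              "rel_friends", "neigh_cohesion", "gender_noncon")
  if (analysis == "exposure_mediator")
    return(c(t2, psycho, "time_gaming", "prob_internet"))
  if (is.null(baseline_outcome))
    stop("baseline_outcome is required at tier 3", call. = FALSE)
  if (analysis == "outcome")
    return(c(t2, psycho, "adhd", baseline_outcome))
  c(t2, psycho, "time_gaming", "prob_internet", baseline_outcome)
}

#' Linear association model with per-SD coefficient
#'
#' Ordinary least squares of a continuous outcome on the exposure and a
#' covariate roster; the reported coefficient is the raw slope multiplied
#' by the exposure's sample SD (or `sd_value`, e.g. the overall-sample SD
#' when fitting within a gender stratum), with a Wald 95% CI.
#'
#' @param data completed (no missing cells among used columns) data.frame.
#' @param outcome,exposure column names.
#' @param covariates character vector of adjustment columns.
#' @param per_sd report per 1 SD of exposure (default) or per raw unit.
#' @param sd_value optional externally supplied SD used for scaling.
#' @param model_label tag stored on the estimate (e.g. `"model3"`).
#' @param stratum tag, e.g. `"overall"`, `"girls"`, `"boys"`.
#' @return an `effect_estimate`.
#' @export
fit_linear_model <- function(data, outcome, exposure,
                             covariates = character(), per_sd = TRUE,
                             sd_value = NULL, model_label = "model",
                             stratum = "overall") {
  used <- c(outcome, exposure, covariates)
  assert_complete(data, used)
  form <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- stats::lm(form, data = data)
  check_design_rank(fit)
  b <- stats::coef(fit)[[exposure]]
  se <- sqrt(stats::vcov(fit)[exposure, exposure])
  sf <- if (per_sd) (sd_value %||% stats::sd(data[[exposure]])) else 1
  z <- stats::qnorm(0.975)
  p <- if (se > 0) 2 * stats::pnorm(-abs(b / se)) else 0
  new_effect_estimate(b * sf, se * sf, (b - z * se) * sf, (b + z * se) * sf,
                      scale = if (per_sd) "beta_per_sd" else "beta",
                      model = model_label, stratum = stratum,
                      n = nrow(data), p = p)
}

#' Exposure-to-mediator association model
#'
#' Convenience wrapper of [fit_linear_model()] with the gaming score as the
#' outcome and the hyperactivity score as the exposure; at tier 3 the
#' roster swaps baseline mental health for the gaming proxies (see
#' [model_roster()]).
#'
#' @inheritParams fit_linear_model
#' @param mediator mediator column name (the model's response).
#' @export
fit_exposure_mediator_model <- function(data, mediator = "gaming",
                                        exposure = "adhd",
                                        covariates = model_roster(
                                          3, "exposure_mediator"),
                                        per_sd = TRUE, sd_value = NULL,
                                        model_label = "model3",
                                        stratum = "overall") {
  fit_linear_model(data, outcome = mediator, exposure = exposure,
                   covariates = covariates, per_sd = per_sd,
                   sd_value = sd_value, model_label = model_label,
                   stratum = stratum)
}

#' Modified Poisson risk-ratio regression
#'
#' Log-link Poisson regression of a binary outcome on a binary exposure
#' and covariates, with robust (HC0 sandwich) standard errors; the
#' exponentiated exposure coefficient is the risk ratio.
#'
#' @param data completed data.frame.
#' @param outcome binary (0/1 or logical) column name.
#' @param exposure binary column name.
#' @param covariates adjustment columns.
#' @param model_label,stratum tags stored on the estimate.
#' @return an `effect_estimate` on the RR scale.
#' @export
fit_poisson_rr <- function(data, outcome, exposure,
                           covariates = character(),
                           model_label = "poisson", stratum = "overall") {
  used <- c(outcome, exposure, covariates)
  assert_complete(data, used)
  y <- as.numeric(data[[outcome]])
  if (!all(y %in% c(0, 1)))
    stop("outcome must be binary", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("outcome is constant (all 0 or all 1)", call. = FALSE)
  df <- data
  df[[outcome]] <- y
  df[[exposure]] <- as.numeric(df[[exposure]])
  form <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- stats::glm(form, data = df, family = stats::poisson())
  check_design_rank(fit)
  b <- stats::coef(fit)[[exposure]]
  se <- sqrt(sandwich::vcovHC(fit, type = "HC0")[exposure, exposure])
  z <- stats::qnorm(0.975)
  new_effect_estimate(exp(b), se, exp(b - z * se), exp(b + z * se),
                      scale = "RR", model = model_label, stratum = stratum,
                      n = nrow(data),
                      p = 2 * stats::pnorm(-abs(b / se)))
}
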