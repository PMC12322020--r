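#' Fit the mediator and outcome regressions for mediation analysis
#'
#' Two ordinary least squares fits with coefficient covariance matrices
#' retained: the mediator on the exposure and covariates, and the outcome
#' on the exposure, mediator, their product (the exposure-mediator
#' interaction) and the covariates. Both mediator and outcome are treated
#' as continuous (well-being reverse-scored upstream so all outcomes are
#' oriented higher-worse).
#'
#' @param data completed data.frame.
#' @param outcome,exposure,mediator column names.
#' @param covariates adjustment roster (see [model_roster()] with
#'   `analysis = "mediation"`).
#' @return list with components `mediator_model` (class `mediator_model`:
#'   `coef` ordered intercept, exposure, covariates; `vcov`; `sigma`) and
#'   `outcome_model` (class `outcome_model`: `coef` ordered intercept,
#'   exposure, mediator, interaction, covariates; `vcov`).
#' @export
fit_mediation_models <- function(data, outcome, exposure, mediator,
                                 covariates = character()) {
  assert_complete(data, c(outcome, exposure, mediator, covariates))
  mform <- stats::reformulate(c(exposure, covariates), response = mediator)
  mfit <- stats::lm(mform, data = data)
  check_design_rank(mfit)
  inter <- paste0(exposure, ":", mediator)
  yform <- stats::reformulate(c(exposure, mediator, covariates, inter),
                              response = outcome)
  yfit <- stats::lm(yform, data = data)
  check_design_rank(yfit)

  m_ord <- c("(Intercept)", exposure,
             setdiff(names(stats::coef(mfit)), c("(Intercept)", exposure)))
  y_all <- names(stats::coef(yfit))
  y_ord <- c("(Intercept)", exposure, mediator, inter,
             setdiff(y_all, c("(Intercept)", exposure, mediator, inter)))
  mm <- structure(list(
    coef = stats::coef(mfit)[m_ord], vcov = stats::vcov(mfit)[m_ord, m_ord],
    sigma = stats::sigma(mfit), exposure = exposure,
    covariates = setdiff(m_ord, c("(Intercept)", exposure)),
    n = nrow(data)), class = "mediator_model")
  om <- structure(list(
    coef = stats::coef(yfit)[y_ord], vcov = stats::vcov(yfit)[y_ord, y_ord],
    exposure = exposure, mediator = mediator, interaction = inter,
    covariates = setdiff(y_ord, c("(Intercept)", exposure, mediator, inter)),
    n = nrow(data)), class = "outcome_model")
  list(mediator_model = mm, outcome_model = om)
}

med_components <- function(mm, om, a0, a1, cbar) {
  if (a1 == a0) stop("a1 must differ from a0", call. = FALSE)
  cn <- mm$covariates
  if (length(cn)) {
    if (is.null(names(cbar)) || !all(cn %in% names(cbar)))
      stop("cbar must be named and cover the mediator-model covariates",
           call. = FALSE)
    cterm <- sum(mm$coef[cn] * cbar[cn])
  } else cterm <- 0
  list(delta = a1 - a0,
       m0 = unname(mm$coef[1] + mm$coef[2] * a0 + cterm),
       alpha1 = unname(mm$coef[2]),
       th1 = unname(om$coef[2]), th2 = unname(om$coef[3]),
       th3 = unname(om$coef[4]))
}

#' Two-way decomposition with exposure-mediator interaction
#'
#' Decomposes the total effect of the exposure contrast `a1` vs `a0` into
#' the pure direct effect and the total indirect effect, evaluated at the
#' covariate vector `cbar`:
#' `pde = (theta1 + theta3 * E[M | a0, cbar]) * (a1 - a0)` and
#' `tie = (theta2 + theta3 * a1) * alpha1 * (a1 - a0)`, with
#' `te = pde + tie` holding to machine precision by construction. When the
#' interaction coefficient is zero the indirect effect reduces to the
#' classical product of coefficients.
#'
#' @param mm,om fitted models from [fit_mediation_models()].
#' @param a0,a1 exposure levels compared (`a1 != a0`).
#' @param cbar named covariate vector (typically sample means).
#' @return object of class `mediation_result` with `te`, `pde`, `tie`,
#'   `pm` (proportion mediated, fraction), `a0`, `a1`, `m0`
#'   (`E[M | a0, cbar]`). `pm` is `NA` with a warning when `te` is zero,
#'   and the result carries attribute `flagged = TRUE` when `te` and `tie`
#'   have opposite signs or `|te|` is near zero.
#' @export
two_way_decompose <- function(mm, om, a0, a1, cbar = NULL) {
  cmp <- med_components(mm, om, a0, a1, cbar)
  pde <- (cmp$th1 + cmp$th3 * cmp$m0) * cmp$delta
  tie <- (cmp$th2 + cmp$th3 * a1) * cmp$alpha1 * cmp$delta
  te <- pde + tie
  pm <- if (te == 0) {
    warning("total effect is zero; proportion mediated undefined",
            call. = FALSE)
    NA_real_
  } else tie / te
  res <- structure(list(te = te, pde = pde, tie = tie, pm = pm,
                        a0 = a0, a1 = a1, m0 = cmp$m0, cbar = cbar),
                   class = "mediation_result")
  flagged <- (is.finite(te) && is.finite(tie) && tie != 0 &&
                sign(te) != sign(tie)) || abs(te) < 1e-10
  attr(res, "flagged") <- flagged
  res
}

#' Delta-method standard errors and CIs for the two-way decomposition
#'
#' Propagates the coefficient covariance matrices of the two fitted models
#' (treated as independent blocks, standard for separately fitted
#' regressions) through the gradients of the pure direct, total indirect
#' and total effects, giving normal-theory 95% CIs. The exposure levels
#' and covariate evaluation point are treated as fixed constants. With no
#' interaction term the indirect-effect SE reduces to the Sobel formula.
#'
#' @inheritParams two_way_decompose
#' @param level confidence level (default 0.95).
#' @return data.frame with rows `te`, `pde`, `tie` and columns `estimate`,
#'   `se`, `ci_low`, `ci_high`, `p`.
#' @export
delta_method_ci <- function(mm, om, a0, a1, cbar = NULL, level = 0.95) {
  cmp <- med_components(mm, om, a0, a1, cbar)
  if (any(!is.finite(mm$vcov)) || any(!is.finite(om$vcov)))
    stop("singular or invalid coefficient covariance", call. = FALSE)
  d <- cmp$delta
  pm_names <- names(mm$coef)  # (Intercept), exposure, covariates...
  po_names <- names(om$coef)  # (Intercept), exposure, mediator, inter, covs

  grad <- function(effect) {
    gm <- stats::setNames(numeric(length(pm_names)), pm_names)
    go <- stats::setNames(numeric(length(po_names)), po_names)
    if (effect %in% c("pde", "te")) {
      go[2] <- go[2] + d                       # theta1
      go[4] <- go[4] + cmp$m0 * d              # theta3 via m0
      gm[1] <- gm[1] + cmp$th3 * d             # alpha0
      gm[2] <- gm[2] + cmp$th3 * a0 * d        # alpha1
      if (length(mm$covariates))
        gm[mm$covariates] <- gm[mm$covariates] +
          cmp$th3 * cbar[mm$covariates] * d    # alpha2
    }
    if (effect %in% c("tie", "te")) {
      go[3] <- go[3] + cmp$alpha1 * d          # theta2
      go[4] <- go[4] + a1 * cmp$alpha1 * d     # theta3
      gm[2] <- gm[2] + (cmp$th2 + cmp$th3 * a1) * d  # alpha1
    }
    list(gm = gm, go = go)
  }

  dec <- two_way_decompose(mm, om, a0, a1, cbar)
  est <- c(te = dec$te, pde = dec$pde, tie = dec$tie)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- lapply(names(est), function(eff) {
    gr <- grad(eff)
    v <- drop(t(gr$gm) %*% mm$vcov %*% gr$gm +
                t(gr$go) %*% om$vcov %*% gr$go)
    se <- sqrt(max(v, 0))
    p <- if (se > 0) 2 * stats::pnorm(-abs(est[[eff]] / se))
         else as.numeric(est[[eff]] == 0)
    data.frame(effect = eff, estimate = est[[eff]], se = se,
               ci_low = est[[eff]] - z * se, ci_high = est[[eff]] + z * se,
               p = p)
  })
  do.call(rbind, out)
}

#' Monte-Carlo counterfactual oracle for the closed-form decomposition
#'
#' Validates the closed-form decomposition by direct simulation of the
#' counterfactuals: draws the mediator under each exposure level from the
#' mediator model's Gaussian law (common residual per subject, so
#' `M(a1) = M(a0) + alpha1 * (a1 - a0)`), evaluates the outcome model's
#' mean function, and averages `Y(a1, M(a0)) - Y(a0, M(a0))` (direct) and
#' `Y(a1, M(a1)) - Y(a1, M(a0))` (indirect).
#'
#' @inheritParams two_way_decompose
#' @param n_draws Monte-Carlo draws (>= 1000).
#' @param seed integer seed.
#' @return list with `nde`, `nie` and their Monte-Carlo standard errors
#'   `se_nde`, `se_nie`.
#' @export
mc_counterfactual_oracle <- function(mm, om, cbar = NULL, a0, a1,
                                     n_draws = 1e5, seed = 1L) {
  if (n_draws < 1000) stop_field("n_draws", "must be >= 1000")
  cmp <- med_components(mm, om, a0, a1, cbar)
  cn_o <- om$covariates
  cterm_o <- if (length(cn_o)) sum(om$coef[cn_o] * cbar[cn_o]) else 0
  yfun <- function(a, m)
    om$coef[[1]] + cmp$th1 * a + cmp$th2 * m + cmp$th3 * a * m + cterm_o
  set.seed(seed)
  eps <- stats::rnorm(n_draws, 0, mm$sigma)
  m_a0 <- cmp$m0 + eps
  m_a1 <- m_a0 + cmp$alpha1 * cmp$delta
  d_dir <- yfun(a1, m_a0) - yfun(a0, m_a0)
  d_ind <- yfun(a1, m_a1) - yfun(a1, m_a0)
  list(nde = mean(d_dir), nie = mean(d_ind),
       se_nde = stats::sd(d_dir) / sqrt(n_draws),
       se_nie = stats::sd(d_ind) / sqrt(n_draws))
}

#' Proportion mediated
#'
#' @param te,tie total and total indirect effects (`te != 0`).
#' @return the proportion mediated as a percentage, `100 * tie / te`; a
#'   warning is issued when `te` and `tie` have opposite signs (the
#'   percentage is then outside 0-100 and hard to interpret).
#' @export
proportion_mediated <- function(te, tie) {
  if (!is.numeric(te) || te == 0)
    stop("total effect is zero; proportion mediated undefined",
         call. = FALSE)
  if (tie != 0 && sign(te) != sign(tie))
    warning("total and indirect effects have opposite signs", call. = FALSE)
  100 * tie / te
}

#' Regression-based causal mediation with exposure-mediator interaction
#'
#' The top-level mediation fit: fits the mediator and outcome regressions,
#' decomposes the effect of a 1 SD increase of the exposure from its mean
#' (by default) into pure direct and total indirect effects at the
#' covariate sample means, attaches delta-method standard errors and CIs,
#' and the proportion mediated.
#'
#' @inheritParams fit_mediation_models
#' @param a0,a1 exposure levels compared; default `a0 = mean(exposure)`,
#'   `a1 = a0 + sd_contrast * sd(exposure)`. Pass explicitly (e.g. values
#'   from the overall sample) when fitting within a gender stratum.
#' @param sd_contrast multiplier of the exposure SD for the default
#'   contrast.
#' @param level confidence level.
#' @return object of class `mediation_fit`; see [summary.mediation_fit()].
#'   Components include the two fitted models, the `mediation_result`, the
#'   delta-method `ci_table`, and `pm_percent`.
#' @export
mediate_twoway <- function(data, outcome, exposure, mediator,
                           covariates = character(), a0 = NULL, a1 = NULL,
                           sd_contrast = 1, level = 0.95) {
  fits <- fit_mediation_models(data, outcome, exposure, mediator, covariates)
  mm <- fits$mediator_model; om <- fits$outcome_model
  a0 <- a0 %||% mean(data[[exposure]])
  a1 <- a1 %||% (a0 + sd_contrast * stats::sd(data[[exposure]]))
  cbar <- if (length(mm$covariates)) {
    X <- stats::model.matrix(stats::reformulate(covariates), data = data)
    colMeans(X[, mm$covariates, drop = FALSE])
  } else NULL
  dec <- two_way_decompose(mm, om, a0, a1, cbar)
  ci <- delta_method_ci(mm, om, a0, a1, cbar, level = level)
  pm <- if (dec$te != 0) proportion_mediated(dec$te, dec$tie) else NA_real_
  structure(list(mediator_model = mm, outcome_model = om,
                 result = dec, ci_table = ci, pm_percent = pm,
                 outcome = outcome, exposure = exposure,
                 mediator = mediator, covariates = covariates,
                 a0 = a0, a1 = a1, n = nrow(data), level = level),
            class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Causal mediation (two-way decomposition): %s -> %s -> %s\n",
              x$exposure, x$mediator, x$outcome))
  cat(sprintf("  n = %d, contrast %.3f -> %.3f\n", x$n, x$a0, x$a1))
  tab <- x$ci_table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-4s %8.4f (95%% CI %8.4f to %8.4f)\n",
                toupper(tab$effect[i]), tab$estimate[i], tab$ci_low[i],
                tab$ci_high[i]))
  cat(sprintf("  proportion mediated: %.1f%%\n", x$pm_percent))
  invisible(x)
}

#' Summary of a mediation fit
#'
#' @param object a `mediation_fit`.
#' @param ... unused.
#' @return the delta-method effect table with the proportion mediated as
#'   attribute `pm_percent`, invisibly printed.
#' @export
summary.mediation_fit <- function(object, ...) {
  tab <- object$ci_table
  attr(tab, "pm_percent") <- object$pm_percent
  attr(tab, "flagged") <- attr(object$result, "flagged")
  tab
}

#' @export
coef.mediation_fit <- function(object, ...) {
  c(te = object$result$te, pde = object$result$pde, tie = object$result$tie)
}

#' @export
confint.mediation_fit <- function(object, parm, level = 0.95, ...) {
  tab <- object$ci_table
  m <- as.matrix(tab[, c("ci_low", "ci_high")])
  rownames(m) <- tab$effect
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}
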