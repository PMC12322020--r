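#' Propensity model and inverse probability weights
#'
#' Logistic regression of a binary exposure group on a covariate roster;
#' each subject's weight is `1/e` if exposed and `1/(1-e)` otherwise,
#' where `e` is the fitted propensity. Fitted probabilities numerically at
#' 0 or 1 (separation) are signalled with the number of subjects affected.
#'
#' @param data completed data.frame.
#' @param exposure binary (0/1 or logical) column name.
#' @param covariates roster; empty for a constant-only model.
#' @return object of class `propensity_weights`: `propensity`, `weight`,
#'   `exposure`, and the fitted `model`.
#' @export
fit_propensity <- function(data, exposure, covariates = character()) {
  assert_complete(data, c(exposure, covariates))
  g <- as.numeric(data[[exposure]])
  if (!all(g %in% c(0, 1))) stop("exposure must be binary", call. = FALSE)
  df <- data
  df[[exposure]] <- g
  form <- stats::reformulate(if (length(covariates)) covariates else "1",
                             response = exposure)
  fit <- stats::glm(form, data = df, family = stats::binomial())
  check_design_rank(fit)
  e <- stats::fitted(fit)
  eps <- 1e-8
  n_sep <- sum(e < eps | e > 1 - eps)
  if (n_sep > 0)
    warning(sprintf("separation-like fitted propensities for %d subject(s)",
                    n_sep), call. = FALSE)
  structure(list(propensity = as.numeric(e),
                 weight = ifelse(g == 1, 1 / e, 1 / (1 - e)),
                 exposure = exposure, model = fit),
            class = "propensity_weights")
}

#' Weighted outcome model and g-formula standardization
#'
#' Fits a weighted canonical-link (logistic) outcome model including the
#' exposure and the covariate roster, predicts every subject's outcome
#' probability under exposure 1 and under exposure 0, and averages the
#' predictions over the full sample to obtain standardized risks, their
#' difference (RD) and ratio (RR). With inverse-probability weights from
#' [fit_propensity()] the estimator is doubly robust; with `weights =
#' NULL` (uniform) it is plain g-formula standardization.
#'
#' @param data completed data.frame.
#' @param outcome binary column name.
#' @param exposure binary column name.
#' @param covariates roster.
#' @param weights a `propensity_weights` object, a numeric vector, or
#'   `NULL` for uniform weights.
#' @return object of class `dr_fit` with `risk1`, `risk0`, `rd`, `rr`.
#' @export
dr_standardize <- function(data, outcome, exposure,
                           covariates = character(), weights = NULL) {
  assert_complete(data, c(outcome, exposure, covariates))
  y <- as.numeric(data[[outcome]])
  g <- as.numeric(data[[exposure]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  if (!all(g %in% c(0, 1))) stop("exposure must be binary", call. = FALSE)
  if (length(unique(g)) < 2)
    stop("an exposure arm is empty", call. = FALSE)
  w <- if (is.null(weights)) rep(1, nrow(data))
       else if (inherits(weights, "propensity_weights")) weights$weight
       else as.numeric(weights)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be positive and finite", call. = FALSE)

  if (length(unique(y)) < 2) {
    risk <- y[1]
    rr <- if (risk == 0) NA_real_ else 1
    if (risk == 0)
      warning("outcome never occurs; risk ratio undefined", call. = FALSE)
    return(structure(list(risk1 = risk, risk0 = risk, rd = 0, rr = rr,
                          outcome = outcome, exposure = exposure,
                          n = nrow(data)), class = "dr_fit"))
  }

  Xc <- stats::model.matrix(
    stats::reformulate(if (length(covariates)) covariates else "1"),
    data = data)
  Xo <- cbind(Xc[, 1, drop = FALSE], g = g, Xc[, -1, drop = FALSE])
  fit <- suppressWarnings(
    stats::glm.fit(Xo, y, weights = w, family = stats::quasibinomial()))
  beta <- fit$coefficients
  if (anyNA(beta))
    stop("rank-deficient outcome design; collinear column(s): ",
         paste(colnames(Xo)[is.na(beta)], collapse = ", "), call. = FALSE)
  X1 <- Xo; X1[, "g"] <- 1
  X0 <- Xo; X0[, "g"] <- 0
  risk1 <- mean(stats::plogis(drop(X1 %*% beta)))
  risk0 <- mean(stats::plogis(drop(X0 %*% beta)))
  rr <- if (risk0 > 0) risk1 / risk0 else {
    warning("reference risk is zero; risk ratio undefined", call. = FALSE)
    NA_real_
  }
  structure(list(risk1 = risk1, risk0 = risk0, rd = risk1 - risk0, rr = rr,
                 outcome = outcome, exposure = exposure, n = nrow(data)),
            class = "dr_fit")
}

# fast single-shot DR point estimate on prebuilt design matrices;
# errors propagate to the caller (bootstrap drops failed replicates)
dr_point_fast <- function(Xp, Xc, g, y, truncate = NULL) {
  fp <- suppressWarnings(
    stats::glm.fit(Xp, g, family = stats::binomial()))
  e <- fp$fitted.values
  w <- ifelse(g == 1, 1 / e, 1 / (1 - e))
  if (!is.null(truncate)) {
    qs <- stats::quantile(w, c(truncate, 1 - truncate))
    w <- clip(w, qs[1], qs[2])
  }
  if (any(!is.finite(w))) stop("non-finite weight")
  Xo <- cbind(Xc[, 1, drop = FALSE], g = g, Xc[, -1, drop = FALSE])
  fo <- suppressWarnings(
    stats::glm.fit(Xo, y, weights = w, family = stats::quasibinomial()))
  beta <- fo$coefficients
  if (anyNA(beta)) stop("rank-deficient replicate")
  X1 <- Xo; X1[, "g"] <- 1
  X0 <- Xo; X0[, "g"] <- 0
  risk1 <- mean(stats::plogis(drop(X1 %*% beta)))
  risk0 <- mean(stats::plogis(drop(X0 %*% beta)))
  c(rd = risk1 - risk0, rr = risk1 / risk0,
    risk1 = risk1, risk0 = risk0)
}

#' Doubly robust risk difference and risk ratio with bootstrap CIs
#'
#' The full doubly robust pipeline: propensity model, inverse probability
#' weights, weighted logistic outcome model, g-formula standardization,
#' and percentile-bootstrap confidence intervals obtained by resampling
#' subjects with replacement and re-running the whole pipeline per
#' replicate. Replicates failing (separation, empty arm, rank deficiency)
#' are dropped and counted; more than 10% drops aborts.
#'
#' @inheritParams dr_standardize
#' @param propensity_covariates roster for the propensity model; defaults
#'   to `covariates`.
#' @param n_boot bootstrap replicates (>= 2); 0 skips the CIs.
#' @param seed integer seed for the resampling.
#' @param truncate_weights optional tail probability (e.g. 0.01) at which
#'   the weights are percentile-truncated; `NULL` (default) leaves weights
#'   untouched.
#' @return a `dr_fit` with percentile CIs `ci_rd`, `ci_rr`, plus `n_boot`
#'   and `n_dropped`.
#' @export
dr_estimate <- function(data, outcome, exposure, covariates = character(),
                        propensity_covariates = covariates,
                        n_boot = 1000L, seed = 1L,
                        truncate_weights = NULL) {
  assert_complete(data, unique(c(outcome, exposure, covariates,
                                 propensity_covariates)))
  y <- as.numeric(data[[outcome]])
  g <- as.numeric(data[[exposure]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  if (!all(g %in% c(0, 1))) stop("exposure must be binary", call. = FALSE)
  if (length(unique(g)) < 2) stop("an exposure arm is empty", call. = FALSE)
  Xp <- stats::model.matrix(
    stats::reformulate(if (length(propensity_covariates))
      propensity_covariates else "1"), data = data)
  Xc <- stats::model.matrix(
    stats::reformulate(if (length(covariates)) covariates else "1"),
    data = data)

  pt <- dr_point_fast(Xp, Xc, g, y, truncate = truncate_weights)
  res <- structure(list(risk1 = pt[["risk1"]], risk0 = pt[["risk0"]],
                        rd = pt[["rd"]], rr = pt[["rr"]],
                        outcome = outcome, exposure = exposure,
                        n = nrow(data), n_boot = 0L, n_dropped = 0L),
                   class = "dr_fit")
  if (n_boot > 0) {
    if (n_boot < 2) stop_field("n_boot", "must be >= 2 (or 0 to skip)")
    set.seed(seed)
    n <- nrow(data)
    draws <- matrix(NA_real_, n_boot, 2)
    dropped <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      est <- tryCatch(
        dr_point_fast(Xp[idx, , drop = FALSE], Xc[idx, , drop = FALSE],
                      g[idx], y[idx], truncate = truncate_weights),
        error = function(e) NULL)
      if (is.null(est) || any(!is.finite(est[c("rd", "rr")])))
        dropped <- dropped + 1L
      else draws[b, ] <- est[c("rd", "rr")]
    }
    if (dropped > 0.10 * n_boot)
      stop(sprintf("%d of %d bootstrap replicates failed", dropped, n_boot),
           call. = FALSE)
    ok <- stats::complete.cases(draws)
    res$ci_rd <- unname(stats::quantile(draws[ok, 1], c(0.025, 0.975)))
    res$ci_rr <- unname(stats::quantile(draws[ok, 2], c(0.025, 0.975)))
    res$n_boot <- as.integer(n_boot)
    res$n_dropped <- dropped
  }
  res
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("Doubly robust estimate: %s ~ %s (n = %d)\n",
              x$outcome, x$exposure, x$n))
  cat(sprintf("  risk1 %.4f  risk0 %.4f\n", x$risk1, x$risk0))
  if (!is.null(x$ci_rd))
    cat(sprintf("  RD %.4f (95%% CI %.4f to %.4f)\n  RR %.3f (95%% CI %.3f to %.3f)  [%d bootstrap, %d dropped]\n",
                x$rd, x$ci_rd[1], x$ci_rd[2], x$rr, x$ci_rr[1], x$ci_rr[2],
                x$n_boot, x$n_dropped))
  else
    cat(sprintf("  RD %.4f   RR %.3f\n", x$rd, x$rr))
  invisible(x)
}

# standardized joint-category risks for exposure x stratum on a prebuilt
# design; s is 0 at the reference stratum
reri_point_fast <- function(Xp, Xc, g, s, y, use_weights) {
  w <- rep(1, length(y))
  if (use_weights) {
    fp <- suppressWarnings(stats::glm.fit(Xp, g, family = stats::binomial()))
    e <- fp$fitted.values
    w <- ifelse(g == 1, 1 / e, 1 / (1 - e))
    if (any(!is.finite(w))) stop("non-finite weight")
  }
  Xo <- cbind(Xc[, 1, drop = FALSE], g = g, s = s, gs = g * s,
              Xc[, -1, drop = FALSE])
  fo <- suppressWarnings(
    stats::glm.fit(Xo, y, weights = w, family = stats::quasibinomial()))
  beta <- fo$coefficients
  if (anyNA(beta)) stop("rank-deficient replicate")
  risk <- function(gv, sv) {
    X <- Xo
    X[, "g"] <- gv; X[, "s"] <- sv; X[, "gs"] <- gv * sv
    mean(stats::plogis(drop(X %*% beta)))
  }
  r00 <- risk(0, 0)
  rr10 <- risk(1, 0) / r00
  rr01 <- risk(0, 1) / r00
  rr11 <- risk(1, 1) / r00
  c(rr10 = rr10, rr01 = rr01, rr11 = rr11,
    reri = rr11 - rr10 - rr01 + 1, rrr = rr11 / (rr10 * rr01))
}

#' Additive and multiplicative interaction (RERI and RRR)
#'
#' Fits the weighted logistic outcome model with a product term between
#' the exposure group and a binary stratum variable (gender), standardizes
#' the four joint-category risks against the common reference category,
#' and reports the relative excess risk due to interaction
#' `RERI = RR11 - RR10 - RR01 + 1` and the ratio of risk ratios
#' `RRR = RR11 / (RR10 * RR01)`, with percentile-bootstrap CIs.
#'
#' @inheritParams dr_estimate
#' @param stratum binary column name (gender).
#' @param reference_stratum the stratum value forming the common reference
#'   (default 1, i.e. boys when `stratum = "male"`).
#' @param propensity_covariates roster for the internal propensity model;
#'   `NULL` gives unweighted (plain g-formula) standardization.
#' @return object of class `interaction_result`: `rr10`, `rr01`, `rr11`,
#'   `reri`, `rrr`, optional `ci_reri`, `ci_rrr`.
#' @export
reri_rrr <- function(data, outcome, exposure, stratum,
                     covariates = character(),
                     propensity_covariates = covariates,
                     reference_stratum = 1,
                     n_boot = 1000L, seed = 1L) {
  assert_complete(data, unique(c(outcome, exposure, stratum, covariates,
                                 propensity_covariates %||% character())))
  y <- as.numeric(data[[outcome]])
  g <- as.numeric(data[[exposure]])
  s <- as.numeric(data[[stratum]] != reference_stratum)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  if (!all(g %in% c(0, 1))) stop("exposure must be binary", call. = FALSE)
  counts <- table(factor(g, 0:1), factor(s, 0:1))
  if (any(counts == 0))
    stop("empty joint exposure-by-stratum category", call. = FALSE)
  use_w <- !is.null(propensity_covariates)
  Xp <- stats::model.matrix(
    stats::reformulate(if (use_w && length(propensity_covariates))
      propensity_covariates else "1"), data = data)
  Xc <- stats::model.matrix(
    stats::reformulate(if (length(covariates)) covariates else "1"),
    data = data)
  pt <- reri_point_fast(Xp, Xc, g, s, y, use_w)
  res <- structure(c(as.list(pt),
                     list(outcome = outcome, exposure = exposure,
                          stratum = stratum,
                          reference_stratum = reference_stratum,
                          n = nrow(data), n_boot = 0L, n_dropped = 0L)),
                   class = "interaction_result")
  if (n_boot > 0) {
    set.seed(seed)
    n <- nrow(data)
    draws <- matrix(NA_real_, n_boot, 2)
    dropped <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      est <- tryCatch(
        reri_point_fast(Xp[idx, , drop = FALSE], Xc[idx, , drop = FALSE],
                        g[idx], s[idx], y[idx], use_w),
        error = function(e) NULL)
      if (is.null(est) || any(!is.finite(est[c("reri", "rrr")])))
        dropped <- dropped + 1L
      else draws[b, ] <- est[c("reri", "rrr")]
    }
    if (dropped > 0.10 * n_boot)
      stop(sprintf("%d of %d bootstrap replicates failed", dropped, n_boot),
           call. = FALSE)
    ok <- stats::complete.cases(draws)
    res$ci_reri <- unname(stats::quantile(draws[ok, 1], c(0.025, 0.975)))
    res$ci_rrr <- unname(stats::quantile(draws[ok, 2], c(0.025, 0.975)))
    res$n_boot <- as.integer(n_boot)
    res$n_dropped <- dropped
  }
  res
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("Interaction of %s and %s on %s (n = %d)\n",
              x$exposure, x$stratum, x$outcome, x$n))
  cat(sprintf("  RR10 %.3f  RR01 %.3f  RR11 %.3f\n", x$rr10, x$rr01, x$rr11))
  if (!is.null(x$ci_reri))
    cat(sprintf("  RERI %.3f (95%% CI %.3f to %.3f)\n  RRR  %.3f (95%% CI %.3f to %.3f)\n",
                x$reri, x$ci_reri[1], x$ci_reri[2],
                x$rrr, x$ci_rrr[1], x$ci_rrr[2]))
  else
    cat(sprintf("  RERI %.3f   RRR %.3f\n", x$reri, x$rrr))
  invisible(x)
}

#' E-value for a risk ratio
#'
#' The minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need with both exposure and outcome to
#' fully explain away an observed risk ratio:
#' `E = RR + sqrt(RR * (RR - 1))` for `RR >= 1`; ratios below 1 are first
#' inverted. For a confidence interval the bound closer to the null is
#' used, and the E-value is 1 when the interval crosses 1.
#'
#' @param rr observed risk ratio (> 0).
#' @param ci_low,ci_high optional 95% CI bounds.
#' @return object of class `evalue_result`: `evalue_point` and (when a CI
#'   is given) `evalue_ci`, both >= 1.
#' @export
e_value <- function(rr, ci_low = NULL, ci_high = NULL) {
  if (!is.numeric(rr) || length(rr) != 1L || !is.finite(rr) || rr <= 0)
    stop("rr must be a single positive number", call. = FALSE)
  ev <- function(r) {
    r <- if (r < 1) 1 / r else r
    if (r == 1) 1 else r + sqrt(r * (r - 1))
  }
  out <- list(evalue_point = ev(rr), evalue_ci = NULL)
  if (!is.null(ci_low) && !is.null(ci_high)) {
    if (ci_low > ci_high) stop("ci_low > ci_high", call. = FALSE)
    out$evalue_ci <- if (ci_low <= 1 && ci_high >= 1) 1
                     else if (rr >= 1) ev(ci_low) else ev(ci_high)
  }
  structure(out, class = "evalue_result")
}

#' @export
print.evalue_result <- function(x, ...) {
  cat(sprintf("E-value (point): %.3f", x$evalue_point))
  if (!is.null(x$evalue_ci)) cat(sprintf("   (CI bound): %.3f", x$evalue_ci))
  cat("\n")
  invisible(x)
}
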