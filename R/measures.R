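#' Scale specification
#'
#' Describes one self- or parent-report instrument: its items, per-item
#' response levels, total-score transform and range. The invariant that the
#' transformed maximum item total equals the top of the stated range is
#' enforced at construction.
#'
#' @param name scale name.
#' @param item_count number of items.
#' @param item_levels numeric vector of admissible per-item scores (shared
#'   by all items).
#' @param total_range length-2 numeric, the closed range of the total.
#' @param transform `"identity"` or `"times4"` (the well-being index sums
#'   items then multiplies by four).
#' @param direction `"higher_worse"` or `"higher_better"`.
#' @return object of class `scale_spec`.
#' @export
scale_spec <- function(name, item_count, item_levels, total_range,
                       transform = c("identity", "times4"),
                       direction = c("higher_worse", "higher_better")) {
  transform <- match.arg(transform)
  direction <- match.arg(direction)
  if (item_count < 1) stop_field("item_count", "must be >= 1")
  mult <- if (transform == "times4") 4 else 1
  top <- item_count * max(item_levels) * mult
  if (!isTRUE(all.equal(top, total_range[2])))
    stop_field("total_range",
               sprintf("max attainable total %g != stated top %g",
                       top, total_range[2]))
  structure(list(name = name, item_count = item_count,
                 item_levels = item_levels, total_range = total_range,
                 transform = transform, direction = direction),
            class = "scale_spec")
}

#' Built-in instrument registry
#'
#' The five instruments used across the three waves: the SDQ
#' hyperactivity/inattention subscale (exposure, 0-10), the nine-item
#' problematic online gaming screen (mediator, 0-9), the SMFQ (depressive
#' symptoms, 0-26), a 14-item CBCL anxiety subset (0-28), the APSS
#' (psychotic experiences, 0-7 in half-point steps) and the WHO-5
#' well-being index (items summed then multiplied by four, 0-100).
#'
#' @return named list of [scale_spec()] objects.
#' @export
scale_registry <- function() {
  list(
    sdq_hyper = scale_spec("sdq_hyper", 5, 0:2, c(0, 10)),
    gaming = scale_spec("gaming", 9, 0:1, c(0, 9)),
    smfq = scale_spec("smfq", 13, 0:2, c(0, 26)),
    cbcl_anxiety = scale_spec("cbcl_anxiety", 14, 0:2, c(0, 28)),
    apss = scale_spec("apss", 7, c(0, 0.5, 1), c(0, 7)),
    who5 = scale_spec("who5", 5, 0:5, c(0, 100), transform = "times4",
                      direction = "higher_better"))
}

#' Score a scale from item responses
#'
#' Sums item responses (one subject as a vector, or subjects x items as a
#' matrix/data.frame), applying the scale's transform. Missing items are
#' not prorated: any `NA` is rejected; item-level missingness is resolved
#' upstream.
#'
#' @param responses numeric vector of length `item_count`, or a matrix /
#'   data.frame with `item_count` columns.
#' @param spec a [scale_spec()].
#' @return numeric total score(s) within the scale's range.
#' @export
score_scale <- function(responses, spec) {
  if (!inherits(spec, "scale_spec")) stop("spec must be a scale_spec")
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1)
  if (ncol(responses) != spec$item_count)
    stop(sprintf("expected %d items, got %d", spec$item_count,
                 ncol(responses)), call. = FALSE)
  for (j in seq_len(ncol(responses))) {
    v <- responses[, j]
    if (anyNA(v)) stop(sprintf("missing response at item %d", j),
                       call. = FALSE)
    bad <- !v %in% spec$item_levels
    if (any(bad))
      stop(sprintf("out-of-range response at item %d: %g", j,
                   v[which(bad)[1]]), call. = FALSE)
  }
  tot <- rowSums(responses)
  if (spec$transform == "times4") tot <- tot * 4
  if (length(tot) == 1L) tot <- unname(tot)
  tot
}

#' Dichotomization cut-offs
#'
#' The case-defining thresholds: problematic gaming high group at a score
#' of four or more symptoms (low 0-3, high 4-9); depression at SMFQ >= 8;
#' anxiety at a T-score of 65 (+1.5 reference SD); psychotic experiences at
#' at least one "yes, definitely" item; diminished well-being at WHO-5
#' <= 50 (configurable to strict `<`; the boundary side is a package
#' convention).
#'
#' @param gaming_high_min,smfq_case_min,anxiety_t_min,apss_definite_min_items,who5_diminished_max
#'   the thresholds.
#' @param who5_strict logical; if `TRUE`, diminished well-being requires
#'   `score < who5_diminished_max` instead of `<=`.
#' @return object of class `cutoff_rules`.
#' @export
cutoff_rules <- function(gaming_high_min = 4, smfq_case_min = 8,
                         anxiety_t_min = 65, apss_definite_min_items = 1,
                         who5_diminished_max = 50, who5_strict = FALSE) {
  rules <- list(gaming_high_min = gaming_high_min,
                smfq_case_min = smfq_case_min,
                anxiety_t_min = anxiety_t_min,
                apss_definite_min_items = apss_definite_min_items,
                who5_diminished_max = who5_diminished_max,
                who5_strict = isTRUE(who5_strict))
  ranges <- list(gaming_high_min = c(0, 9), smfq_case_min = c(0, 26),
                 anxiety_t_min = c(0, 200), apss_definite_min_items = c(1, 7),
                 who5_diminished_max = c(0, 100))
  for (f in names(ranges)) {
    v <- rules[[f]]
    if (!is.numeric(v) || v < ranges[[f]][1] || v > ranges[[f]][2])
      stop_field(f, "threshold outside its scale's range")
  }
  structure(rules, class = "cutoff_rules")
}

#' Dichotomize the gaming score
#'
#' @param score integer gaming symptom count, 0-9.
#' @param rules a [cutoff_rules()].
#' @return factor with levels `low`, `high`; high iff
#'   `score >= gaming_high_min` (default 4).
#' @export
dichotomize_gaming <- function(score, rules = cutoff_rules()) {
  if (any(!is.finite(score)) || any(score < 0 | score > 9) ||
      any(score != floor(score)))
    stop("gaming score must be an integer in 0-9", call. = FALSE)
  factor(ifelse(score >= rules$gaming_high_min, "high", "low"),
         levels = c("low", "high"))
}

#' T-score standardization
#'
#' Linear standardization to mean 50, SD 10: a raw score 1.5 reference SDs
#' above the reference mean maps to 65.
#'
#' @param x raw score(s).
#' @param ref_mean,ref_sd reference mean and (positive) SD.
#' @return T-score(s).
#' @export
t_score <- function(x, ref_mean, ref_sd) {
  if (!is.numeric(ref_sd) || any(ref_sd <= 0))
    stop_field("ref_sd", "must be > 0")
  50 + 10 * (x - ref_mean) / ref_sd
}

#' Reverse-score the well-being index
#'
#' Reflects WHO-5 so that higher values indicate worse well-being, as used
#' in the mediation analyses (where all outcomes are oriented
#' higher-worse).
#'
#' @param score WHO-5 total(s), 0-100.
#' @return `100 - score`.
#' @export
reverse_wellbeing <- function(score) {
  if (any(!is.finite(score)) || any(score < 0 | score > 100))
    stop("well-being score must lie in 0-100", call. = FALSE)
  100 - score
}

#' Case indicators for the four outcomes
#'
#' Applies the cut-offs of [cutoff_rules()] to a table of total scores:
#' depression iff SMFQ >= 8; anxiety iff T-score >= 65, where the T
#' reference is by default computed from the supplied sample itself
#' (gender-specific when `gender` is given); psychotic experiences iff at
#' least one "yes, definitely" item when item-level data are supplied in
#' `apss_items`, else iff the half-point total is >= 1 (a definite item
#' contributes 1.0); diminished well-being iff WHO-5 <= 50.
#'
#' @param scores data.frame with any of the columns `smfq`, `anxiety`,
#'   `apss`, `who5` (total scores).
#' @param rules a [cutoff_rules()].
#' @param gender optional 0/1 vector (1 = boy) for gender-specific anxiety
#'   reference statistics.
#' @param anxiety_ref optional explicit reference, `list(mean=, sd=)`, or a
#'   list of two such lists named `"0"` and `"1"` for gender-specific
#'   references; overrides the sample-based default.
#' @param apss_items optional subjects x 7 matrix of APSS item scores
#'   (0 / 0.5 / 1).
#' @return data.frame of logical columns (per outcome present):
#'   `depression_case`, `anxiety_case`, `psychotic_case`,
#'   `wellbeing_diminished`.
#' @export
dichotomize_outcome <- function(scores, rules = cutoff_rules(),
                                gender = NULL, anxiety_ref = NULL,
                                apss_items = NULL) {
  out <- list()
  if (!is.null(scores$smfq)) {
    if (any(scores$smfq < 0 | scores$smfq > 26, na.rm = TRUE))
      stop("SMFQ score outside 0-26", call. = FALSE)
    out$depression_case <- scores$smfq >= rules$smfq_case_min
  }
  if (!is.null(scores$anxiety)) {
    x <- scores$anxiety
    if (any(x < 0 | x > 28, na.rm = TRUE))
      stop("anxiety score outside 0-28", call. = FALSE)
    tt <- rep(NA_real_, length(x))
    groups <- if (is.null(gender)) rep(0, length(x)) else gender
    for (gval in unique(groups)) {
      idx <- groups == gval
      ref <- anxiety_ref
      if (!is.null(ref) && is.null(ref$mean)) ref <- ref[[as.character(gval)]]
      if (is.null(ref))
        ref <- list(mean = mean(x[idx], na.rm = TRUE),
                    sd = stats::sd(x[idx], na.rm = TRUE))
      if (is.null(ref$mean) || is.null(ref$sd) || !is.finite(ref$sd) ||
          ref$sd <= 0)
        stop("anxiety T-score reference statistics unavailable",
             call. = FALSE)
      tt[idx] <- t_score(x[idx], ref$mean, ref$sd)
    }
    out$anxiety_case <- tt >= rules$anxiety_t_min
  }
  if (!is.null(apss_items)) {
    apss_items <- as.matrix(apss_items)
    out$psychotic_case <-
      rowSums(apss_items == 1) >= rules$apss_definite_min_items
  } else if (!is.null(scores$apss)) {
    if (any(scores$apss < 0 | scores$apss > 7, na.rm = TRUE))
      stop("APSS score outside 0-7", call. = FALSE)
    out$psychotic_case <- scores$apss >= rules$apss_definite_min_items
  }
  if (!is.null(scores$who5)) {
    x <- scores$who5
    if (any(x < 0 | x > 100, na.rm = TRUE))
      stop("WHO-5 score outside 0-100", call. = FALSE)
    out$wellbeing_diminished <-
      if (rules$who5_strict) x < rules$who5_diminished_max
      else x <= rules$who5_diminished_max
  }
  as.data.frame(out)
}

#' Cronbach's alpha
#'
#' Internal consistency `(k/(k-1)) * (1 - sum(item variances) /
#' var(total))` for a subjects x items matrix with no missing cells.
#'
#' @param item_matrix numeric matrix or data.frame, >= 2 subjects and >= 2
#'   items.
#' @return alpha (<= 1).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need >= 2 subjects and >= 2 items", call. = FALSE)
  if (anyNA(m)) stop("item matrix contains missing values", call. = FALSE)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0)
    stop("total-score variance is zero; alpha undefined", call. = FALSE)
  item_vars <- apply(m, 2, stats::var)
  (k / (k - 1)) * (1 - sum(item_vars) / total_var)
}
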