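#' Pipeline configuration
#'
#' Bundles every stage's settings and seeds so a pipeline run is fully
#' reproducible: the cohort generation config, the imputation config, the
#' bootstrap size and seed, and which outcomes and model tiers to fit.
#'
#' @param generation a [cohort_config()].
#' @param imputation an [impute_config()].
#' @param n_boot bootstrap replicates for the doubly robust stage.
#' @param boot_seed seed for all bootstrap resampling.
#' @param outcomes outcome scales analyzed.
#' @param tiers model tiers fitted in the association stage.
#' @param stratify_gender also run gender-stratified association and
#'   mediation analyses.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(generation = cohort_config(),
                            imputation = impute_config(),
                            n_boot = 500L, boot_seed = 1L,
                            outcomes = c("smfq", "anxiety", "apss", "who5"),
                            tiers = 1:3, stratify_gender = TRUE) {
  if (!inherits(generation, "cohort_config"))
    stop_field("generation", "must be a cohort_config")
  if (!inherits(imputation, "impute_config"))
    stop_field("imputation", "must be an impute_config")
  if (!is.numeric(boot_seed) || length(boot_seed) != 1L)
    stop_field("boot_seed", "must be a single integer")
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  structure(list(generation = generation, imputation = imputation,
                 n_boot = as.integer(n_boot),
                 boot_seed = as.integer(boot_seed),
                 outcomes = outcomes, tiers = tiers,
                 stratify_gender = isTRUE(stratify_gender)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `generation`, `imputation`, `n_boot`, `boot_seed`,
#' `outcomes`, `tiers`, `stratify_gender`; the `generation` and
#' `imputation` mappings are passed as arguments to [cohort_config()] and
#' [impute_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- do.call(cohort_config, as.list(y$generation))
  imp <- do.call(impute_config, as.list(y$imputation))
  args <- y[setdiff(names(y), c("generation", "imputation"))]
  args <- args[intersect(names(args),
                         c("n_boot", "boot_seed", "outcomes", "tiers",
                           "stratify_gender"))]
  args$outcomes <- if (is.null(args$outcomes)) {
    c("smfq", "anxiety", "apss", "who5")
  } else unlist(args$outcomes)
  if (!is.null(args$tiers)) args$tiers <- unlist(args$tiers)
  do.call(pipeline_config, c(list(generation = gen, imputation = imp), args))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate, blank, impute, score, and the three analysis
#' stages end to end, writing tidy result files to `out_dir`:
#' `cohort.csv` (+ config sidecar), `completed.csv`,
#' `associations.tsv` (per-SD linear models by outcome, tier and
#' stratum), `exposure_mediator.tsv`, `dr_estimates.tsv` (standardized
#' risks, RD, RR and bootstrap CIs per outcome), `interaction.json`
#' (RERI/RRR), `evalues.json`, `mediation.tsv` (TE/PDE/TIE with
#' delta-method CIs by outcome and stratum), `proportion_mediated.json`,
#' and `manifest.json` (config, config hash, seeds, package version).
#' A fixed configuration yields byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results and file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be created by pipeline_config()", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  raw <- run_stage("generate", {
    tab <- generate_cohort(config$generation)
    tab <- apply_missingness(tab, config$generation)
    write_cohort(tab, p("cohort.csv"))
    tab
  })

  completed <- run_stage("impute", {
    done <- rf_impute(raw, config$imputation)
    utils::write.csv(done, p("completed.csv"), row.names = FALSE)
    done
  })

  scored <- run_stage("score", {
    rules <- cutoff_rules()
    cases <- dichotomize_outcome(
      data.frame(smfq = completed$smfq_w3, anxiety = completed$anxiety_w3,
                 apss = completed$apss_w3, who5 = completed$who5_w3),
      rules = rules, gender = completed$male)
    completed$gaming_high <-
      as.numeric(dichotomize_gaming(round(completed$gaming),
                                    rules) == "high")
    completed$who5_w3_rev <- reverse_wellbeing(completed$who5_w3)
    completed$who5_w1_rev <- reverse_wellbeing(completed$who5_w1)
    for (v in names(cases)) completed[[v]] <- as.numeric(cases[[v]])
    completed
  })
  case_col <- c(smfq = "depression_case", anxiety = "anxiety_case",
                apss = "psychotic_case", who5 = "wellbeing_diminished")
  w3_col <- c(smfq = "smfq_w3", anxiety = "anxiety_w3", apss = "apss_w3",
              who5 = "who5_w3")
  w1_col <- c(smfq = "smfq_w1", anxiety = "anxiety_w1", apss = "apss_w1",
              who5 = "who5_w1")

  strata <- list(overall = rep(TRUE, nrow(scored)))
  if (config$stratify_gender) {
    strata$girls <- scored$male == 0
    strata$boys <- scored$male == 1
  }
  sd_gaming <- stats::sd(scored$gaming)
  sd_adhd <- stats::sd(scored$adhd)

  assoc <- run_stage("associate", {
    rows <- list()
    for (o in config$outcomes) for (tier in config$tiers)
      for (s in names(strata)) {
        covs <- model_roster(tier, "outcome", baseline_outcome = w1_col[[o]])
        if (s != "overall") covs <- setdiff(covs, "male")
        est <- fit_linear_model(scored[strata[[s]], , drop = FALSE],
                                outcome = w3_col[[o]], exposure = "gaming",
                                covariates = covs, sd_value = sd_gaming,
                                model_label = paste0("model", tier),
                                stratum = s)
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = s, outcome = o, model = est$model, beta = est$point,
          ci_low = est$ci_low, ci_high = est$ci_high, p = est$p, n = est$n)
      }
    tab <- do.call(rbind, rows)
    write_tsv(tab, p("associations.tsv"))
    tab
  })

  expmed <- run_stage("exposure_mediator", {
    rows <- list()
    for (tier in config$tiers) for (s in names(strata)) {
      covs <- model_roster(tier, "exposure_mediator")
      if (s != "overall") covs <- setdiff(covs, "male")
      est <- fit_exposure_mediator_model(
        scored[strata[[s]], , drop = FALSE], covariates = covs,
        sd_value = sd_adhd, model_label = paste0("model", tier), stratum = s)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, model = est$model, beta = est$point,
        ci_low = est$ci_low, ci_high = est$ci_high, p = est$p, n = est$n)
    }
    tab <- do.call(rbind, rows)
    write_tsv(tab, p("exposure_mediator.tsv"))
    tab
  })

  dr <- run_stage("doubly_robust", {
    rows <- list(); ev <- list(); inter <- list()
    for (o in config$outcomes) {
      covs <- model_roster(3, "outcome", baseline_outcome = w1_col[[o]])
      fit <- dr_estimate(scored, outcome = case_col[[o]],
                         exposure = "gaming_high", covariates = covs,
                         n_boot = config$n_boot, seed = config$boot_seed)
      rows[[o]] <- data.frame(
        outcome = o, risk1 = fit$risk1, risk0 = fit$risk0,
        rd = fit$rd, rd_low = fit$ci_rd[1], rd_high = fit$ci_rd[2],
        rr = fit$rr, rr_low = fit$ci_rr[1], rr_high = fit$ci_rr[2],
        n_boot = fit$n_boot, n_dropped = fit$n_dropped)
      evr <- e_value(fit$rr, fit$ci_rr[1], fit$ci_rr[2])
      ev[[o]] <- list(rr = fit$rr, evalue_point = evr$evalue_point,
                      evalue_ci = evr$evalue_ci)
      ir <- tryCatch(
        reri_rrr(scored, outcome = case_col[[o]], exposure = "gaming_high",
                 stratum = "male",
                 covariates = setdiff(covs, "male"),
                 propensity_covariates = setdiff(covs, "male"),
                 n_boot = config$n_boot, seed = config$boot_seed),
        error = function(e) NULL)
      inter[[o]] <- if (is.null(ir)) list(error = "estimation failed")
        else list(rr10 = ir$rr10, rr01 = ir$rr01, rr11 = ir$rr11,
                  reri = ir$reri, reri_ci = ir$ci_reri,
                  rrr = ir$rrr, rrr_ci = ir$ci_rrr)
    }
    tab <- do.call(rbind, rows)
    write_tsv(tab, p("dr_estimates.tsv"))
    jsonlite::write_json(ev, p("evalues.json"), auto_unbox = TRUE,
                         digits = NA)
    jsonlite::write_json(inter, p("interaction.json"), auto_unbox = TRUE,
                         digits = NA)
    list(estimates = tab, evalues = ev, interaction = inter)
  })

  med <- run_stage("mediate", {
    a0 <- mean(scored$adhd); a1 <- a0 + sd_adhd
    rows <- list(); pms <- list()
    for (o in config$outcomes) {
      ycol <- if (o == "who5") "who5_w3_rev" else w3_col[[o]]
      bcol <- if (o == "who5") "who5_w1_rev" else w1_col[[o]]
      covs <- model_roster(3, "mediation", baseline_outcome = bcol)
      for (s in names(strata)) {
        use_covs <- if (s == "overall") covs else setdiff(covs, "male")
        fit <- mediate_twoway(scored[strata[[s]], , drop = FALSE],
                              outcome = ycol, exposure = "adhd",
                              mediator = "gaming", covariates = use_covs,
                              a0 = a0, a1 = a1)
        tab <- fit$ci_table
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = s, outcome = o, effect = tab$effect,
          estimate = tab$estimate, ci_low = tab$ci_low,
          ci_high = tab$ci_high, p = tab$p)
        if (s == "overall") pms[[o]] <- fit$pm_percent
      }
    }
    tab <- do.call(rbind, rows)
    write_tsv(tab, p("mediation.tsv"))
    jsonlite::write_json(pms, p("proportion_mediated.json"),
                         auto_unbox = TRUE, digits = NA)
    list(effects = tab, proportion_mediated = pms)
  })

  run_stage("manifest", {
    cfg_json <- jsonlite::toJSON(
      list(generation = unclass(config$generation),
           imputation = unclass(config$imputation),
           n_boot = config$n_boot, boot_seed = config$boot_seed,
           outcomes = config$outcomes, tiers = config$tiers,
           stratify_gender = config$stratify_gender),
      auto_unbox = TRUE, digits = NA, null = "null")
    manifest <- list(
      package = "drmediate",
      version = as.character(utils::packageVersion("drmediate")),
      config_hash = fnv1a32(as.character(cfg_json)),
      seeds = list(generation = config$generation$seed,
                   imputation = config$imputation$seed,
                   bootstrap = config$boot_seed),
      config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
      outputs = c("cohort.csv", "completed.csv", "associations.tsv",
                  "exposure_mediator.tsv", "dr_estimates.tsv",
                  "evalues.json", "interaction.json", "mediation.tsv",
                  "proportion_mediated.json"))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  })

  invisible(list(cohort = raw, completed = scored, associations = assoc,
                 exposure_mediator = expmed, dr = dr, mediation = med,
                 out_dir = out_dir))
}
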