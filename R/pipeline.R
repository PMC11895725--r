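#' Pipeline configuration
#'
#' Bundles every stage parameter for [run_pipeline()]. Inputs come either
#' from a simulation config (`sim`) or from a directory of tables previously
#' written by [write_population()] (`input_dir`).
#'
#' @param sim Optional [sim_config()] for an end-to-end synthetic run.
#' @param input_dir Optional directory of input tables (used when `sim` is
#'   `NULL`).
#' @param out_dir Output directory for stage artifacts; `NULL` skips writing.
#' @param cutoff_days Fill cutoff in days (default 30).
#' @param search_horizon_days Matching horizon in days (default 365).
#' @param washout_days New-user washout (default 365).
#' @param followup_censor_days Follow-up censoring horizon (default 90).
#' @param phq9_lookback_days PHQ-9 lookback window (default 14).
#' @param propensity A [propensity_options()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            out_dir = NULL, cutoff_days = 30L,
                            search_horizon_days = 365L, washout_days = 365L,
                            followup_censor_days = 90L,
                            phq9_lookback_days = 14L,
                            propensity = propensity_options()) {
  if (is.null(sim) && is.null(input_dir)) {
    stop_config("either `sim` or `input_dir` must be supplied", "input_dir")
  }
  if (is.null(sim) && !dir.exists(input_dir)) {
    stop_config(sprintf("input directory does not exist: %s", input_dir),
                "input_dir")
  }
  for (field in c("cutoff_days", "search_horizon_days", "washout_days",
                  "followup_censor_days", "phq9_lookback_days")) {
    value <- get(field)
    if (!is_pos_int(value)) {
      stop_config(sprintf("`%s` must be a positive integer", field), field)
    }
  }
  if (cutoff_days > search_horizon_days) {
    stop_config("`cutoff_days` cannot exceed `search_horizon_days`",
                "cutoff_days")
  }
  structure(
    list(sim = sim, input_dir = input_dir, out_dir = out_dir,
         cutoff_days = as.integer(cutoff_days),
         search_horizon_days = as.integer(search_horizon_days),
         washout_days = as.integer(washout_days),
         followup_censor_days = as.integer(followup_censor_days),
         phq9_lookback_days = as.integer(phq9_lookback_days),
         propensity = propensity),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "rxfill_pipeline_error", parent = e)
  })
}

#' Run the full linkage-and-analysis pipeline
#'
#' Executes, in order: simulate (or load) the event tables; match
#' prescriptions to dispensings and label fills by the day cutoff; build the
#' new-user cohort (washout, age, completeness); assemble the 22 contextual
#' covariates; compute the fillers-versus-non-fillers balance table; fit the
#' lasso propensity model and derive IPW weights; and estimate unweighted
#' and weighted Cox hazard ratios (plus Kaplan-Meier curves) for time to a
#' follow-up visit with the prescribing provider. Artifacts are written as
#' delimited text after each stage when `out_dir` is set.
#'
#' @param config A [pipeline_config()].
#' @return An `rxfill_report` list: `attrition`, `fill_summary`, `balance`,
#'   `propensity`, `hr_unweighted`, `hr_weighted`, `km_fill`,
#'   `km_followup`, `covariates`, `links`, `cohort`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  population <- run_stage("simulate", {
    if (!is.null(config$sim)) generate_population(config$sim)
    else read_population(config$input_dir)
  })
  vocab <- new_vocabulary(population$crosswalk)
  study_window <- population$config$study_window %||%
    range(population$prescriptions$rx_date)
  capture_window <- population$config$capture_window %||%
    (study_window + 365L)

  links <- run_stage("link", {
    match_fills(population$prescriptions, population$dispensings, vocab,
                search_horizon_days = config$search_horizon_days,
                cutoff_days = config$cutoff_days)
  })

  cohort <- run_stage("cohort", {
    identify_new_users(population$prescriptions, population$dispensings,
                       population$patients, population$encounters, vocab,
                       study_window, config$washout_days) |>
      apply_completeness_filter(population$encounters, capture_window)
  })

  covariates <- run_stage("covariates", {
    build_covariate_table(cohort, population$patients, population$encounters,
                          population$diagnoses, population$phq9,
                          population$prescriptions, links, vocab,
                          config$phq9_lookback_days)
  })

  balance <- run_stage("balance", balance_table(covariates))

  cohort_links <- links$links |> semi_join(cohort, by = "rx_id")
  matched <- cohort_links |> filter(!is.na(.data$days_to_fill))
  fill_summary <- tibble(
    n_cohort = nrow(cohort_links),
    n_filled_within_cutoff = sum(cohort_links$filled_within_cutoff),
    pct_filled_within_cutoff =
      100 * mean(cohort_links$filled_within_cutoff),
    n_matched = nrow(matched),
    pct_same_day_among_fillers = 100 * mean(matched$days_to_fill == 0),
    pct_within_week_among_fillers = 100 * mean(matched$days_to_fill <= 7),
    cutoff_days = config$cutoff_days
  )

  model <- run_stage("propensity", {
    fit_propensity_model(covariates, config$propensity)
  })
  weights <- run_stage("weights", {
    ipw_weights(model$scores$ps, covariates$fill_status,
                config$propensity$clip_bounds)
  })

  followup <- run_stage("followup", {
    derive_followup(cohort, population$encounters,
                    config$followup_censor_days)
  })
  fill_of <- setNames(covariates$fill_status, covariates$patient_id)
  grp <- unname(fill_of[followup$patient_id])

  hr_unweighted <- run_stage("cox", {
    marginal_cox_hr(followup$time, followup$event, grp)
  })
  w_of <- setNames(weights, covariates$patient_id)
  hr_weighted <- run_stage("cox-weighted", {
    marginal_cox_hr(followup$time, followup$event, grp,
                    weights = unname(w_of[followup$patient_id]))
  })

  km_fill <- run_stage("km-fill", {
    cohort_result <- links
    cohort_result$links <- cohort_links
    time_to_fill_curve(cohort_result, config$search_horizon_days)
  })
  km_followup <- run_stage("km-followup", {
    list(
      filled = km_estimator(followup$time[grp], followup$event[grp]),
      not_filled = km_estimator(followup$time[!grp], followup$event[!grp])
    )
  })

  report <- structure(
    list(
      attrition = attrition_log(cohort),
      fill_summary = fill_summary,
      balance = balance,
      propensity = model,
      hr_unweighted = hr_unweighted,
      hr_weighted = hr_weighted,
      km_fill = km_fill,
      km_followup = km_followup,
      covariates = covariates,
      links = links,
      cohort = cohort,
      manifest = tibble(
        config_hash = rlang::hash(config),
        sim_seed = config$sim$seed %||% NA_integer_,
        propensity_seed = config$propensity$seed
      )
    ),
    class = "rxfill_report"
  )

  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
  }
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(df, name) {
    readr::write_csv(df, file.path(dir, paste0(name, ".csv")), na = "")
  }
  out(report$attrition, "attrition")
  out(report$fill_summary, "fill_summary")
  out(as_tibble(report$balance), "balance")
  out(report$links$links, "links")
  out(report$cohort, "cohort")
  out(report$covariates, "covariates")
  out(tibble(feature = names(report$propensity$coefficients),
             coefficient = unname(report$propensity$coefficients)),
      "propensity_coefficients")
  out(report$propensity$scores, "propensity_scores")
  hr_row <- function(x, label) {
    tibble(model = label, hr = x$hr, ci_low = x$ci_low, ci_high = x$ci_high,
           log_hr_se = x$log_hr_se, n = x$n, n_events = x$n_events)
  }
  out(bind_rows(hr_row(report$hr_unweighted, "unweighted"),
                hr_row(report$hr_weighted, "ipw")), "hazard_ratios")
  out(as_tibble(report$km_fill), "km_fill")
  out(bind_rows(
    as_tibble(report$km_followup$filled) |> mutate(group = "filled"),
    as_tibble(report$km_followup$not_filled) |> mutate(group = "not_filled")
  ), "km_followup")
  out(report$manifest, "manifest")
  invisible(dir)
}

#' @export
print.rxfill_report <- function(x, ...) {
  fs <- x$fill_summary
  cat("rxfill pipeline report\n")
  cat(sprintf("  cohort: %d patients; %d (%.1f%%) filled within %d days\n",
              fs$n_cohort, fs$n_filled_within_cutoff,
              fs$pct_filled_within_cutoff, fs$cutoff_days))
  cat(sprintf("  among matched fills: %.1f%% same-day, %.1f%% within 7 days\n",
              fs$pct_same_day_among_fillers, fs$pct_within_week_among_fillers))
  cat(sprintf("  covariates flagged imbalanced (SMD > 0.10): %d of %d\n",
              sum(x$balance$imbalance), nrow(x$balance)))
  cat(sprintf("  propensity test AUROC: %.3f\n", x$propensity$test_auroc))
  cat("  "); print(x$hr_unweighted)
  cat("  "); print(x$hr_weighted)
  invisible(x)
}
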