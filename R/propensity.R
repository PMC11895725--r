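#' Propensity model fitting options
#'
#' @param cv_folds Folds for cross-validating the lasso penalty (default 5).
#' @param train_fraction Fraction of rows in the training split (default 0.9,
#'   i.e. a 9:1 train:test ratio).
#' @param seed Seed controlling the stratified split and fold assignment.
#' @param clip_bounds Length-2 numeric; predicted probabilities are clipped
#'   into this interval before weighting.
#' @param lambda Optional fixed penalty; `NULL` (default) selects the penalty
#'   minimizing cross-validated binomial deviance.
#' @return A `propensity_options` list.
#' @export
propensity_options <- function(cv_folds = 5L, train_fraction = 0.9,
                               seed = 1L, clip_bounds = c(0.01, 0.99),
                               lambda = NULL) {
  if (!is_pos_int(cv_folds) || cv_folds < 2) {
    stop_config("`cv_folds` must be an integer >= 2", "cv_folds")
  }
  if (!is_prop(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_config("`train_fraction` must lie strictly in (0, 1)",
                "train_fraction")
  }
  if (!is.numeric(clip_bounds) || length(clip_bounds) != 2 ||
      clip_bounds[1] <= 0 || clip_bounds[2] >= 1 ||
      clip_bounds[1] >= clip_bounds[2]) {
    stop_config("`clip_bounds` must satisfy 0 < low < high < 1",
                "clip_bounds")
  }
  structure(list(cv_folds = as.integer(cv_folds),
                 train_fraction = train_fraction, seed = seed,
                 clip_bounds = clip_bounds, lambda = lambda),
            class = "propensity_options")
}

# Design matrix for the propensity model: one-hot categoricals against their
# first (reference) level, median-imputed BMI with a missingness indicator.
propensity_design <- function(rows, bmi_median = NULL) {
  df <- rows |>
    select(dplyr::all_of(COVARIATE_NAMES)) |>
    mutate(bmi_missing = is.na(.data$bmi))
  if (is.null(bmi_median)) bmi_median <- median(df$bmi, na.rm = TRUE)
  df$bmi[is.na(df$bmi)] <- bmi_median
  x <- model.matrix(~ ., data = df)[, -1, drop = FALSE]
  list(x = x, bmi_median = bmi_median)
}

#' Fit a cross-validated lasso propensity model for fill status
#'
#' Splits rows into training and testing sets (stratified on the fill label),
#' selects the L1 penalty by k-fold cross-validated binomial deviance on the
#' training split, evaluates discrimination on the held-out split, and
#' produces clipped predicted fill probabilities (propensity scores) for all
#' rows.
#'
#' @param rows Covariate table from [build_covariate_table()] (must contain
#'   `fill_status` and the 22 covariates).
#' @param options A [propensity_options()].
#' @return A `propensity_model`: coefficients at the selected penalty, the
#'   penalty value, `test_auroc`, and a `scores` tibble (`patient_id`, `ps`,
#'   `fill_status`, `split`).
#' @export
fit_propensity_model <- function(rows, options = propensity_options()) {
  check_columns(rows, c("fill_status", COVARIATE_NAMES), "covariate table")
  if (nrow(rows) < 50) {
    stop_analysis("need at least 50 rows to fit the propensity model")
  }
  y <- as.numeric(rows$fill_status)
  if (length(unique(y)) < 2) {
    stop_analysis("fill status must contain both classes")
  }

  with_seed(options$seed, {
    idx_pos <- which(y == 1)
    idx_neg <- which(y == 0)
    n_test_pos <- max(1L, round(length(idx_pos) * (1 - options$train_fraction)))
    n_test_neg <- max(1L, round(length(idx_neg) * (1 - options$train_fraction)))
    test_idx <- sort(c(sample(idx_pos, n_test_pos),
                       sample(idx_neg, n_test_neg)))
    train_idx <- setdiff(seq_along(y), test_idx)

    design <- propensity_design(rows[train_idx, , drop = FALSE])
    x_train <- design$x
    design_all <- propensity_design(rows, bmi_median = design$bmi_median)
    x_all <- design_all$x

    foldid <- sample(rep_len(seq_len(options$cv_folds), length(train_idx)))
    if (is.null(options$lambda)) {
      cv <- glmnet::cv.glmnet(x_train, y[train_idx], family = "binomial",
                              alpha = 1, foldid = foldid,
                              type.measure = "deviance")
      lambda <- cv$lambda.min
      fit <- cv$glmnet.fit
    } else {
      lambda <- options$lambda
      fit <- glmnet::glmnet(x_train, y[train_idx], family = "binomial",
                            alpha = 1)
    }

    ps_all <- as.numeric(predict(fit, newx = x_all, s = lambda,
                                 type = "response"))
    ps_all <- pmin(pmax(ps_all, options$clip_bounds[1]),
                   options$clip_bounds[2])
    test_auroc <- auroc(ps_all[test_idx], y[test_idx] == 1)

    beta <- as.matrix(coef(fit, s = lambda))
    structure(
      list(
        coefficients = setNames(beta[, 1], rownames(beta)),
        lambda = lambda,
        options = options,
        bmi_median = design$bmi_median,
        test_auroc = test_auroc,
        scores = tibble(
          patient_id = rows$patient_id %||% as.character(seq_along(y)),
          ps = ps_all,
          fill_status = y == 1,
          split = ifelse(seq_along(y) %in% test_idx, "test", "train")
        )
      ),
      class = "propensity_model"
    )
  })
}

#' @export
print.propensity_model <- function(x, ...) {
  nz <- sum(x$coefficients[-1] != 0)
  cat(sprintf(
    "<propensity_model> lambda = %.4g, %d active features, test AUROC = %.3f\n",
    x$lambda, nz, x$test_auroc
  ))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counted as one half. Invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) class labels; both classes must be present.
#' @return Scalar in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop_domain("scores and labels must have equal length")
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop_domain("both classes must be present to compute the AUROC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Inverse probability of treatment weights (ATE)
#'
#' Fillers receive `1/ps`, non-fillers `1/(1-ps)`, after clipping the
#' propensity scores into `clip_bounds`.
#'
#' @param ps Propensity scores in `[0, 1]`.
#' @param fill_status Logical treatment indicator.
#' @param clip_bounds Length-2 clipping interval (default `c(0.01, 0.99)`).
#' @return Positive numeric weights.
#' @export
ipw_weights <- function(ps, fill_status, clip_bounds = c(0.01, 0.99)) {
  if (any(ps < 0 | ps > 1, na.rm = TRUE) || anyNA(ps)) {
    stop_domain("propensity scores must lie in [0, 1] and be non-missing")
  }
  ps <- pmin(pmax(ps, clip_bounds[1]), clip_bounds[2])
  ifelse(fill_status, 1 / ps, 1 / (1 - ps))
}

#' Product-limit (Kaplan-Meier) survival estimator
#'
#' Wraps the standard product-limit estimator; when `weights` are supplied,
#' at-risk and event counts are weight sums, giving the IPW-adjusted curve.
#'
#' @param times Non-negative event/censoring times.
#' @param events Logical event indicator (`FALSE` = right-censored).
#' @param weights Optional positive case weights (default all 1).
#' @return A `km_curve` tibble: `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimator <- function(times, events, weights = NULL) {
  if (any(times < 0)) stop_domain("times must be non-negative")
  if (length(times) != length(events)) {
    stop_domain("times and events must have equal length")
  }
  if (!is.null(weights) && any(weights <= 0)) {
    stop_domain("weights must be strictly positive")
  }
  df <- data.frame(time = times, event = as.numeric(events))
  df$.w <- if (is.null(weights)) rep(1, nrow(df)) else weights
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df,
                           weights = df$.w, conf.type = "none")
  out <- tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    survival = fit$surv
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Marginal (optionally weighted) Cox hazard ratio between two groups
#'
#' Single-covariate Cox proportional-hazards fit with the Efron tie
#' correction. With case weights (e.g. from [ipw_weights()]) a robust
#' sandwich variance is used for the confidence interval, as required for
#' valid inference under inverse probability weighting.
#'
#' @param times Follow-up times.
#' @param events Logical event indicator.
#' @param group Logical group indicator (`TRUE` = filled).
#' @param weights Optional positive case weights.
#' @param conf_level Confidence level (default 0.95).
#' @return A `weighted_cox_result` list: `hr`, `ci_low`, `ci_high`,
#'   `log_hr`, `log_hr_se`, `n`, `n_events`, `weighted`.
#' @export
marginal_cox_hr <- function(times, events, group, weights = NULL,
                            conf_level = 0.95) {
  events <- as.logical(events)
  group <- as.logical(group)
  if (sum(events & group) == 0 || sum(events & !group) == 0) {
    stop_analysis("need at least one event in each group")
  }
  df <- data.frame(time = times, event = as.numeric(events),
                   grp = as.numeric(group))
  weighted <- !is.null(weights)
  df$.w <- if (weighted) weights else rep(1, nrow(df))
  fit <- survival::coxph(survival::Surv(time, event) ~ grp, data = df,
                         weights = df$.w, ties = "efron", robust = weighted)
  beta <- unname(coef(fit))
  se <- sqrt(diag(fit$var))[1]  # robust variance when weighted
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      hr = exp(beta),
      ci_low = exp(beta - z * se),
      ci_high = exp(beta + z * se),
      log_hr = beta,
      log_hr_se = se,
      n = nrow(df),
      n_events = sum(events),
      weighted = weighted,
      conf_level = conf_level
    ),
    class = "weighted_cox_result"
  )
}

#' @export
print.weighted_cox_result <- function(x, ...) {
  cat(sprintf(
    "%s HR %.3f (%d%% CI %.3f-%.3f), %d events / %d subjects\n",
    if (x$weighted) "IPW-weighted" else "Marginal",
    x$hr, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n_events, x$n
  ))
  invisible(x)
}

#' Observed time to follow-up visit with the prescribing provider
#'
#' The follow-up event is the first encounter with the index prescriber
#' strictly after the index date; times are administratively censored at
#' `censor_days`.
#'
#' @param cohort Index events (needs `patient_id`, `index_date`,
#'   `prescriber_id`).
#' @param encounters Encounters table.
#' @param censor_days Censoring horizon in days (default 90).
#' @return Tibble `patient_id`, `time`, `event`.
#' @export
derive_followup <- function(cohort, encounters, censor_days = 90L) {
  check_columns(cohort, c("patient_id", "index_date", "prescriber_id"),
                "cohort")
  obs <- encounters |>
    inner_join(select(cohort, "patient_id", "index_date", "prescriber_id"),
               by = "patient_id", relationship = "many-to-many") |>
    filter(.data$provider_id == .data$prescriber_id,
           .data$date > .data$index_date,
           .data$date <= .data$index_date + censor_days) |>
    group_by(.data$patient_id) |>
    summarise(time = as.integer(min(.data$date - .data$index_date)),
              .groups = "drop")
  cohort |>
    select("patient_id") |>
    left_join(obs, by = "patient_id") |>
    mutate(event = !is.na(.data$time),
           time = ifelse(is.na(.data$time), as.integer(censor_days),
                         .data$time))
}
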