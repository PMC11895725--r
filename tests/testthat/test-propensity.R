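test_that("AUROC matches brute-force pair counting", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)),
               0.5)
  # brute force over the 4 positive-negative pairs: only 0.9>0.4 and 0.9>0.8
  expect_equal(auroc(c(0.9, 0.4, 0.35, 0.8), c(TRUE, FALSE, TRUE, FALSE)),
               0.5)
  set.seed(9)
  scores <- runif(40)
  labels <- runif(40) < 0.4
  brute <- mean(outer(scores[labels], scores[!labels],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auroc(scores, labels), brute)
  expect_error(auroc(scores, rep(TRUE, 40)), class = "rxfill_domain_error")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(12)
  scores <- rnorm(60)
  labels <- runif(60) < 0.5
  base <- auroc(scores, labels)
  expect_equal(auroc(exp(scores), labels), base)
  expect_equal(auroc(qlogis(plogis(scores)), labels), base)
})

test_that("IPW weights follow the ATE formula with clipping", {
  expect_equal(ipw_weights(c(0.5, 0.5), c(TRUE, FALSE)), c(2, 2))
  expect_equal(ipw_weights(0.8, TRUE), 1.25)
  # ps below the clip bound is raised to it before inversion
  expect_equal(ipw_weights(0.001, TRUE, clip_bounds = c(0.01, 0.99)), 100)
  expect_equal(ipw_weights(0.999, FALSE, clip_bounds = c(0.01, 0.99)), 100)
  expect_error(ipw_weights(1.2, TRUE), class = "rxfill_domain_error")
})

test_that("product-limit estimator matches the brute-force oracle", {
  # frozen 10-observation fixture with ties and censoring
  times <- c(1, 1, 2, 3, 3, 4, 5, 5, 5, 7)
  events <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE)
  curve <- km_estimator(times, events)
  expect_equal(curve$time, c(1, 2, 3, 4, 5, 7))
  expect_equal(curve$survival, c(0.9, 0.7875, 0.675, 0.54, 0.27, 0.27))
  # random fixtures against the oracle, plus monotonicity
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:30, 1)
    t <- sample(0:15, n, replace = TRUE)
    e <- runif(n) < 0.7
    got <- km_estimator(t, e)
    want <- km_oracle(t, e)
    expect_equal(got$time, want$time)
    expect_equal(got$survival, want$survival, tolerance = 1e-10)
    expect_true(all(diff(got$survival) <= 1e-12))
    expect_true(all(got$survival >= -1e-12 & got$survival <= 1))
  }
})

test_that("weighted product-limit reduces to unweighted at unit weights", {
  set.seed(5)
  t <- rexp(40, 0.1)
  e <- runif(40) < 0.6
  expect_equal(km_estimator(t, e, weights = rep(1, 40)),
               km_estimator(t, e))
  # and matches the weighted oracle with non-unit weights
  w <- runif(40, 0.5, 3)
  got <- km_estimator(t, e, weights = w)
  want <- km_oracle(t, e, weights = w)
  expect_equal(got$survival, want$survival, tolerance = 1e-10)
})

test_that("single censored observation keeps survival at one", {
  curve <- km_estimator(3, FALSE)
  expect_equal(curve$survival, 1)
  expect_error(km_estimator(-1, TRUE), class = "rxfill_domain_error")
})

test_that("Cox HR is one for symmetric groups and flips sign on relabel", {
  times <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  events <- rep(TRUE, 10)
  group <- rep(c(TRUE, FALSE), each = 5)
  fit <- marginal_cox_hr(times, events, group)
  expect_equal(fit$hr, 1, tolerance = 1e-8)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  set.seed(14)
  t <- rexp(120, rate = 0.05 * exp(0.5 * rep(0:1, 60)))
  e <- t < 60
  t <- pmin(t, 60)
  g <- rep(c(FALSE, TRUE), 60)
  a <- marginal_cox_hr(t, e, g)
  b <- marginal_cox_hr(t, e, !g)
  expect_equal(a$log_hr, -b$log_hr, tolerance = 1e-6)
})

test_that("unit weights leave the Cox point estimate unchanged", {
  set.seed(15)
  t <- rexp(100, 0.05)
  e <- t < 50
  t <- pmin(t, 50)
  g <- runif(100) < 0.5
  plain <- marginal_cox_hr(t, e, g)
  unitw <- marginal_cox_hr(t, e, g, weights = rep(1, 100))
  expect_equal(unitw$hr, plain$hr, tolerance = 1e-8)
  expect_true(unitw$weighted)
  expect_error(marginal_cox_hr(c(1, 2), c(TRUE, FALSE), c(TRUE, FALSE)),
               class = "rxfill_analysis_error")
})

test_that("propensity fit is deterministic and discriminates when signal exists", {
  pop <- generate_population(sim_config(n_patients = 800, seed = 51))
  vocab <- load_crosswalk(default_crosswalk_path())
  links <- match_fills(pop$prescriptions, pop$dispensings, vocab)
  cohort <- identify_new_users(pop$prescriptions, pop$dispensings,
                               pop$patients, pop$encounters, vocab,
                               pop$config$study_window) |>
    apply_completeness_filter(pop$encounters, pop$config$capture_window)
  rows <- build_covariate_table(cohort, pop$patients, pop$encounters,
                                pop$diagnoses, pop$phq9, pop$prescriptions,
                                links, vocab)
  m1 <- fit_propensity_model(rows, propensity_options(seed = 3))
  m2 <- fit_propensity_model(rows, propensity_options(seed = 3))
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$scores$ps, m2$scores$ps)
  expect_gt(m1$test_auroc, 0.6)
  expect_true(all(m1$scores$ps >= 0.01 & m1$scores$ps <= 0.99))
  # single-class labels are an analysis error
  bad <- rows
  bad$fill_status <- TRUE
  expect_error(fit_propensity_model(bad), class = "rxfill_analysis_error")
})

test_that("propensity scores are uninformative when labels are independent", {
  pop <- generate_population(sim_config(
    n_patients = 600, seed = 52,
    fill_model_coefficients = c(intercept = 0.5),
    nonfill_rate_target = NULL
  ))
  vocab <- load_crosswalk(default_crosswalk_path())
  links <- match_fills(pop$prescriptions, pop$dispensings, vocab)
  cohort <- identify_new_users(pop$prescriptions, pop$dispensings,
                               pop$patients, pop$encounters, vocab,
                               pop$config$study_window) |>
    apply_completeness_filter(pop$encounters, pop$config$capture_window)
  rows <- build_covariate_table(cohort, pop$patients, pop$encounters,
                                pop$diagnoses, pop$phq9, pop$prescriptions,
                                links, vocab)
  m <- fit_propensity_model(rows, propensity_options(seed = 4))
  # null case: held-out AUROC near one half
  expect_lt(abs(m$test_auroc - 0.5), 0.15)
})

test_that("observed follow-up times equal the generator truth", {
  pop <- generate_population(noise_free_config(n = 250, seed = 61))
  vocab <- load_crosswalk(default_crosswalk_path())
  cohort <- identify_new_users(pop$prescriptions, pop$dispensings,
                               pop$patients, pop$encounters, vocab,
                               pop$config$study_window) |>
    apply_completeness_filter(pop$encounters, pop$config$capture_window)
  fu <- derive_followup(cohort, pop$encounters, pop$config$censor_days)
  truth <- pop$truth[match(fu$patient_id, pop$truth$patient_id), ]
  expect_equal(fu$event, truth$followup_event)
  expect_equal(fu$time, truth$followup_time)
})
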