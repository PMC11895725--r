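#' Configuration for the synthetic EHR population generator
#'
#' Defines every parameter of the simulated study environment: a pediatric
#' population receiving one new (index) psychotropic prescription at an
#' outpatient visit during a one-year study window, a covariate-dependent
#' binary fill process, a fill-delay distribution massed at day 0, imperfect
#' dispensing capture (non-participating pharmacies, decoy fills), and a
#' proportional-hazards follow-up-visit process censored at 90 days.
#'
#' @param n_patients Number of patients (one index prescription each).
#' @param seed Integer RNG seed; the same config is byte-identical on rerun.
#' @param study_window Length-2 `Date` vector, the index (prescribing) year.
#' @param capture_window Length-2 `Date` vector, the completeness year: only
#'   patients with an encounter here have dispensing data reliably captured.
#' @param fill_model_coefficients Named numeric vector of log-odds effects on
#'   the probability of ever filling; may include an `intercept` entry. See
#'   Details for recognised covariate names.
#' @param nonfill_rate_target Proportion of patients who never fill. When
#'   non-`NULL`, the intercept is calibrated by root-finding so the mean fill
#'   probability equals `1 - nonfill_rate_target`; `NULL` uses the supplied
#'   `intercept` entry as-is. `0` / `1` force everyone / no one to fill.
#' @param delay_mixture List with `p_same_day` (probability a filler fills on
#'   day 0), `p_within_week_given_fill` (cumulative probability by day 7), and
#'   `tail_rate` (geometric rate for delays beyond day 0; `NULL` derives it
#'   from the within-week mass).
#' @param decoy_dispensing_rate Per-patient probability of an unrelated
#'   (unmatchable) dispensing record.
#' @param coverage_miss_rate Probability that a true fill is never recorded
#'   (e.g. a non-participating pharmacy).
#' @param prior_use_rate Per-patient probability of a psychotropic dispensing
#'   inside the washout window, making the index prescription non-incident.
#' @param capture_encounter_rate Probability of an encounter during
#'   `capture_window` (independent of the follow-up process).
#' @param extra_rx_rates Named numeric `c(filled=, not_filled=)`: Poisson means
#'   for additional same-year psychotropic prescriptions after the index one
#'   (drives the prescriptions-in-year covariate; set to zero for single-
#'   prescription populations).
#' @param followup_log_hr True log hazard ratio of a follow-up visit for
#'   fillers versus non-fillers.
#' @param followup_coefficients Optional named numeric vector of covariate
#'   log-hazard effects on follow-up (same names as
#'   `fill_model_coefficients`); non-zero values create confounding.
#' @param baseline_followup_hazard Baseline follow-up hazard per day.
#' @param censor_days Administrative censoring horizon for follow-up (days).
#' @param washout_days Lookback window defining a new user (days).
#' @param ssri_fraction Fraction of index prescriptions that are SSRIs.
#' @param bmi_missing_rate Fraction of patients with missing BMI.
#' @param vocabulary Optional `medication_vocabulary`; defaults to the
#'   synthetic crosswalk shipped with the package.
#'
#' @details Recognised covariate names for `fill_model_coefficients` and
#' `followup_coefficients`: `age_z`, `bmi_z`, `adi_z` (standardized with fixed
#' centers/scales 12/3, 22/4, 3.5/2.5), `sex_male`, `payer_public`,
#' `payer_selfpay`, `provider_physician`, `specialty_primary_care`,
#' `clinic_primary_care`, `clinic_behavioral`, `anxiety`, `depression`,
#' `adhd`, `headache`, `ssri`, `phq9_taken`, `wcv_prior_year`,
#' `wcv_index_year`, `outpatient_prior_year`, `inpatient_prior_year`,
#' `ed_prior_year`, plus `intercept`.
#'
#' Default marginal rates mirror a pediatric psychotropic new-user population:
#' 77.8% of patients fill, 81.2% of fillers fill same-day and 91.3% within a
#' week, and the follow-up hazard ratio is 1.5.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 1254,
                       seed = 1L,
                       study_window = as.Date(c("2021-01-01", "2021-12-31")),
                       capture_window = as.Date(c("2022-01-01", "2022-12-31")),
                       fill_model_coefficients = c(
                         intercept = 0,
                         anxiety = 1.5,
                         ssri = 1.1,
                         wcv_prior_year = 1.0,
                         clinic_primary_care = 1.4,
                         specialty_primary_care = 0.8,
                         phq9_taken = 0.5,
                         payer_public = -1.0,
                         sex_male = -0.5,
                         bmi_z = -0.45,
                         adi_z = -0.55
                       ),
                       nonfill_rate_target = 0.222,
                       delay_mixture = list(p_same_day = 0.812,
                                            p_within_week_given_fill = 0.913,
                                            tail_rate = NULL),
                       decoy_dispensing_rate = 0.05,
                       coverage_miss_rate = 0.035,
                       prior_use_rate = 0.05,
                       capture_encounter_rate = 0.9,
                       extra_rx_rates = c(filled = 0.9, not_filled = 0.25),
                       followup_log_hr = log(1.5),
                       followup_coefficients = NULL,
                       baseline_followup_hazard = 0.0065,
                       censor_days = 90L,
                       washout_days = 365L,
                       ssri_fraction = 0.856,
                       bmi_missing_rate = 0.05,
                       vocabulary = NULL) {
  config <- list(
    n_patients = n_patients, seed = seed,
    study_window = study_window, capture_window = capture_window,
    fill_model_coefficients = fill_model_coefficients,
    nonfill_rate_target = nonfill_rate_target,
    delay_mixture = delay_mixture,
    decoy_dispensing_rate = decoy_dispensing_rate,
    coverage_miss_rate = coverage_miss_rate,
    prior_use_rate = prior_use_rate,
    capture_encounter_rate = capture_encounter_rate,
    extra_rx_rates = extra_rx_rates,
    followup_log_hr = followup_log_hr,
    followup_coefficients = followup_coefficients,
    baseline_followup_hazard = baseline_followup_hazard,
    censor_days = censor_days, washout_days = washout_days,
    ssri_fraction = ssri_fraction, bmi_missing_rate = bmi_missing_rate,
    vocabulary = vocabulary
  )
  validate_sim_config(config)
  config$delay_mixture$tail_rate <- delay_tail_rate(config$delay_mixture)
  structure(config, class = "sim_config")
}

delay_tail_rate <- function(mix) {
  if (!is.null(mix$tail_rate)) return(mix$tail_rate)
  ps <- mix$p_same_day
  pw <- mix$p_within_week_given_fill
  if (ps >= 1) return(0.5)  # never used: all fills are same-day
  q <- (pw - ps) / (1 - ps)  # P(delay <= 7 | delay > 0)
  1 - (1 - q)^(1 / 7)
}

validate_sim_config <- function(config) {
  req_prop <- c("nonfill_rate_target", "decoy_dispensing_rate",
                "coverage_miss_rate", "prior_use_rate",
                "capture_encounter_rate", "ssri_fraction", "bmi_missing_rate")
  for (field in req_prop) {
    value <- config[[field]]
    if (field == "nonfill_rate_target" && is.null(value)) next
    if (!is_prop(value)) {
      stop_config(sprintf("`%s` must be a proportion in [0, 1]", field), field)
    }
  }
  if (!is_pos_int(config$n_patients)) {
    stop_config("`n_patients` must be a positive integer", "n_patients")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1 || is.na(config$seed)) {
    stop_config("`seed` must be a single integer", "seed")
  }
  for (field in c("study_window", "capture_window")) {
    win <- config[[field]]
    if (!inherits(win, "Date") || length(win) != 2 || win[1] > win[2]) {
      stop_config(sprintf("`%s` must be an ordered length-2 Date vector", field), field)
    }
  }
  mix <- config$delay_mixture
  if (!is_prop(mix$p_same_day) || !is_prop(mix$p_within_week_given_fill) ||
      mix$p_within_week_given_fill < mix$p_same_day) {
    stop_config("`delay_mixture` proportions must satisfy 0 <= p_same_day <= p_within_week_given_fill <= 1",
                "delay_mixture")
  }
  if (!is.null(mix$tail_rate) &&
      (!is.numeric(mix$tail_rate) || mix$tail_rate <= 0 || mix$tail_rate >= 1)) {
    stop_config("`delay_mixture$tail_rate` must lie in (0, 1)", "delay_mixture")
  }
  if (!is.numeric(config$baseline_followup_hazard) ||
      config$baseline_followup_hazard <= 0) {
    stop_config("`baseline_followup_hazard` must be strictly positive",
                "baseline_followup_hazard")
  }
  for (field in c("censor_days", "washout_days")) {
    if (!is_pos_int(config[[field]])) {
      stop_config(sprintf("`%s` must be a positive integer", field), field)
    }
  }
  if (!is.numeric(config$extra_rx_rates) || length(config$extra_rx_rates) != 2 ||
      any(config$extra_rx_rates < 0)) {
    stop_config("`extra_rx_rates` must be two non-negative Poisson means",
                "extra_rx_rates")
  }
  coefs <- config$fill_model_coefficients
  if (!is.numeric(coefs) || is.null(names(coefs)) || any(!nzchar(names(coefs)))) {
    stop_config("`fill_model_coefficients` must be a named numeric vector",
                "fill_model_coefficients")
  }
  invisible(config)
}

# Map coefficient names to per-patient numeric design columns.
design_column <- function(truth, name) {
  switch(name,
    age_z = (truth$age - 12) / 3,
    bmi_z = ifelse(is.na(truth$bmi), 0, (truth$bmi - 22) / 4),
    adi_z = (truth$adi_state_rank - 3.5) / 2.5,
    sex_male = as.numeric(truth$sex == "Male"),
    payer_public = as.numeric(truth$payer == "Public"),
    payer_selfpay = as.numeric(truth$payer == "Self-pay"),
    provider_physician = as.numeric(truth$provider_type == "Physician"),
    specialty_primary_care = as.numeric(truth$prescriber_specialty == "Primary care"),
    clinic_primary_care = as.numeric(truth$clinic_type == "Primary care"),
    clinic_behavioral = as.numeric(truth$clinic_type == "Behavioral health"),
    anxiety = as.numeric(truth$dx_anxiety),
    depression = as.numeric(truth$dx_depression),
    adhd = as.numeric(truth$dx_adhd),
    headache = as.numeric(truth$dx_headache),
    ssri = as.numeric(truth$ssri),
    phq9_taken = as.numeric(truth$phq9_severity != "Not taken"),
    wcv_prior_year = as.numeric(truth$wcv_prior_year),
    wcv_index_year = as.numeric(truth$wcv_index_year),
    outpatient_prior_year = as.numeric(truth$outpatient_prior_year),
    inpatient_prior_year = as.numeric(truth$inpatient_prior_year),
    ed_prior_year = as.numeric(truth$ed_prior_year),
    stop_config(sprintf("unknown covariate `%s` in coefficient vector", name),
                name)
  )
}

linear_predictor <- function(truth, coefs) {
  coefs <- coefs[setdiff(names(coefs), "intercept")]
  lp <- numeric(nrow(truth))
  for (name in names(coefs)) {
    lp <- lp + coefs[[name]] * design_column(truth, name)
  }
  lp
}

#' Generate a synthetic EHR population with known ground truth
#'
#' Draws demographics, diagnoses, service-use history, a covariate-dependent
#' fill indicator, fill delays, recorded/missed/decoy dispensings, and a
#' follow-up-visit process, then assembles the event tables a real extraction
#' would provide (patients, encounters, prescriptions, dispensings, PHQ-9
#' scores, diagnoses) together with a per-prescription truth table.
#'
#' @param config A [sim_config()].
#' @return A `sim_population` list with elements `patients`, `encounters`,
#'   `prescriptions`, `dispensings`, `phq9`, `diagnoses`, `crosswalk`
#'   (tibble of vocabulary entries), `truth`, and `config`.
#' @export
generate_population <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, unclass(config))
  }
  validate_sim_config(config)
  vocab <- config$vocabulary %||% load_crosswalk(default_crosswalk_path())
  with_seed(config$seed, generate_population_impl(config, vocab))
}

generate_population_impl <- function(config, vocab) {
  n <- config$n_patients
  win <- config$study_window
  cwin <- config$capture_window
  win_days <- as.integer(win[2] - win[1])
  prior_year_start <- win[1] - 365L

  patient_id <- sprintf("P%05d", seq_len(n))
  index_date <- win[1] + sample.int(win_days + 1L, n, replace = TRUE) - 1L

  age_weights <- c(1, 2, 2, 3, 3, 4, 6, 10, 14, 16, 14, 13, 12)
  age <- sample(5:17, n, replace = TRUE, prob = age_weights)
  birth_date <- index_date - ceiling(age * 365.25) -
    sample.int(301L, n, replace = TRUE) + 1L

  sex <- sample(SEX_LEVELS, n, TRUE, prob = c(0.668, 0.332))
  race <- sample(RACE_LEVELS, n, TRUE, prob = c(0.109, 0.028, 0.193, 0.558, 0.112))
  payer <- sample(PAYER_LEVELS, n, TRUE, prob = c(0.445, 0.534, 0.021))
  provider_type <- sample(PROVIDER_LEVELS, n, TRUE, prob = c(0.743, 0.257))
  specialty <- sample(SPECIALTY_LEVELS, n, TRUE, prob = c(0.827, 0.045, 0.120, 0.008))
  clinic <- sample(CLINIC_LEVELS, n, TRUE, prob = c(0.728, 0.080, 0.112, 0.080))
  bmi <- round(rlnorm(n, meanlog = log(22), sdlog = 0.2), 2)
  bmi[runif(n) < config$bmi_missing_rate] <- NA_real_
  adi <- sample(1:10, n, TRUE,
                prob = c(0.14, 0.18, 0.17, 0.13, 0.11, 0.08, 0.06, 0.05, 0.04, 0.04))

  dx_depression <- runif(n) < 0.261
  dx_anxiety    <- runif(n) < 0.534
  dx_adhd       <- runif(n) < 0.140
  dx_headache   <- runif(n) < 0.148

  wcv_prior  <- runif(n) < 0.431
  wcv_index  <- runif(n) < 0.578
  outp_prior <- runif(n) < 0.766
  inpt_prior <- runif(n) < 0.008
  ed_prior   <- runif(n) < 0.044

  phq9_taken <- runif(n) < 0.494
  phq9_cat_draw <- sample(1:5, n, TRUE, prob = c(0.215, 0.203, 0.213, 0.202, 0.167))
  bin_lo <- c(0L, 5L, 10L, 15L, 20L)[phq9_cat_draw]
  bin_hi <- c(4L, 9L, 14L, 19L, 27L)[phq9_cat_draw]
  phq9_score <- as.integer(bin_lo + floor(runif(n) * (bin_hi - bin_lo + 1L)))
  phq9_score[!phq9_taken] <- NA_integer_
  phq9_offset <- sample.int(15L, n, replace = TRUE) - 1L  # 0..14 days pre-index

  # Drug assignment: SSRI class with configured marginal, ingredient uniform
  # within class.
  classes <- vocab_classes(vocab)
  ssri_cuis <- names(classes)[!is.na(classes) & classes == "SSRI"]
  other_cuis <- setdiff(names(vocab$index), ssri_cuis)
  if (length(ssri_cuis) == 0 || length(other_cuis) == 0) {
    stop_config("vocabulary must contain both SSRI and non-SSRI RxCUIs",
                "vocabulary")
  }
  is_ssri <- runif(n) < config$ssri_fraction
  rxcui <- character(n)
  rxcui[is_ssri]  <- sample(ssri_cuis,  sum(is_ssri),  replace = TRUE)
  rxcui[!is_ssri] <- sample(other_cuis, sum(!is_ssri), replace = TRUE)
  name_of_cui <- vocab$entries |>
    distinct(.data$rxcui, .keep_all = TRUE)
  cui_names <- setNames(name_of_cui$drug_name, name_of_cui$rxcui)
  drug_name <- unname(cui_names[rxcui])

  truth <- tibble(
    patient_id = patient_id,
    rx_id = sprintf("RX%05d", seq_len(n)),
    index_date = index_date,
    age = age, sex = sex, race_ethnicity = race, bmi = bmi,
    adi_state_rank = adi, payer = payer, provider_type = provider_type,
    prescriber_specialty = specialty, clinic_type = clinic,
    dx_depression = dx_depression, dx_anxiety = dx_anxiety,
    dx_adhd = dx_adhd, dx_headache = dx_headache,
    ssri = is_ssri,
    phq9_score = phq9_score,
    phq9_severity = as.character(categorize_phq9(phq9_score)),
    n_rx_at_index = 1L,
    n_rx_in_year = 1L,
    wcv_prior_year = wcv_prior, wcv_index_year = wcv_index,
    outpatient_prior_year = outp_prior, inpatient_prior_year = inpt_prior,
    ed_prior_year = ed_prior
  )

  # --- fill process -----------------------------------------------------
  lp <- linear_predictor(truth, config$fill_model_coefficients)
  target <- config$nonfill_rate_target
  if (is.null(target)) {
    intercept <- config$fill_model_coefficients[["intercept"]] %||% 0
    fill_prob <- plogis(intercept + lp)
  } else if (target <= 0) {
    fill_prob <- rep(1, n)
  } else if (target >= 1) {
    fill_prob <- rep(0, n)
  } else {
    intercept <- uniroot(
      function(a) mean(plogis(a + lp)) - (1 - target),
      interval = c(-30, 30), tol = 1e-10
    )$root
    fill_prob <- plogis(intercept + lp)
  }
  fill_true <- runif(n) < fill_prob

  mix <- config$delay_mixture
  same_day <- runif(n) < mix$p_same_day
  delay <- ifelse(same_day, 0L, 1L + rgeom(n, mix$tail_rate))
  delay <- as.integer(delay)
  delay[!fill_true] <- NA_integer_
  recorded <- fill_true & (runif(n) >= config$coverage_miss_rate)

  # --- follow-up process ------------------------------------------------
  lp_fu <- if (is.null(config$followup_coefficients)) {
    numeric(n)
  } else {
    linear_predictor(truth, config$followup_coefficients)
  }
  rate <- config$baseline_followup_hazard *
    exp(config$followup_log_hr * as.numeric(fill_true) + lp_fu)
  t_raw <- ceiling(rexp(n, rate = rate))
  followup_event <- t_raw <= config$censor_days
  followup_time <- as.integer(pmin(t_raw, config$censor_days))

  # --- noise channels ---------------------------------------------------
  prior_use <- runif(n) < config$prior_use_rate
  prior_offset <- sample(30:300, n, replace = TRUE)
  decoy <- runif(n) < config$decoy_dispensing_rate
  decoy_date <- win[1] + sample.int(as.integer(cwin[2] - win[1]) + 1L, n,
                                    replace = TRUE) - 1L
  has_cap <- runif(n) < config$capture_encounter_rate
  cap_date <- cwin[1] + sample.int(as.integer(cwin[2] - cwin[1]) + 1L, n,
                                   replace = TRUE) - 1L

  # Extra (non-index) same-year prescriptions.
  extra_mean <- ifelse(fill_true, config$extra_rx_rates[["filled"]],
                       config$extra_rx_rates[["not_filled"]])
  n_extra <- rpois(n, extra_mean)
  days_left <- as.integer(win[2] - index_date)
  n_extra[days_left <= 0] <- 0L
  truth$n_rx_in_year <- 1L + n_extra

  # --- assemble event tables -------------------------------------------
  prescriber <- sprintf("PRV%03d", sample.int(200L, n, replace = TRUE))

  patients <- tibble(
    patient_id = patient_id, birth_date = birth_date, sex = sex,
    race_ethnicity = race, bmi = bmi, adi_state_rank = adi
  )

  enc_index <- tibble(
    patient_id = patient_id, date = index_date, enc_type = "outpatient",
    provider_id = prescriber, provider_type = provider_type,
    prescriber_specialty = specialty, clinic_type = clinic, payer = payer
  )

  svc_encounter <- function(flag, type, start, span_days) {
    k <- sum(flag)
    tibble(
      patient_id = patient_id[flag],
      date = start + sample.int(span_days, k, replace = TRUE) - 1L,
      enc_type = type, provider_id = "EXT000",
      provider_type = "Other", prescriber_specialty = "Unknown",
      clinic_type = "Unknown", payer = payer[flag]
    )
  }
  enc_service <- bind_rows(
    svc_encounter(wcv_prior,  "well_child", prior_year_start, 365L),
    svc_encounter(wcv_index,  "well_child", win[1], win_days + 1L),
    svc_encounter(outp_prior, "outpatient", prior_year_start, 365L),
    svc_encounter(inpt_prior, "inpatient",  prior_year_start, 365L),
    svc_encounter(ed_prior,   "ed",         prior_year_start, 365L)
  )

  enc_followup <- tibble(
    patient_id = patient_id[followup_event],
    date = index_date[followup_event] + followup_time[followup_event],
    enc_type = "outpatient", provider_id = prescriber[followup_event],
    provider_type = provider_type[followup_event],
    prescriber_specialty = specialty[followup_event],
    clinic_type = clinic[followup_event], payer = payer[followup_event]
  )

  enc_capture <- tibble(
    patient_id = patient_id[has_cap], date = cap_date[has_cap],
    enc_type = "outpatient", provider_id = "EXT000",
    provider_type = "Other", prescriber_specialty = "Unknown",
    clinic_type = "Unknown", payer = payer[has_cap]
  )

  # Extra prescriptions need their own (non-prescriber) encounters so they
  # never masquerade as follow-up visits.
  extra_idx <- rep.int(seq_len(n), n_extra)
  extra_offset <- integer(0)
  if (length(extra_idx) > 0) {
    extra_offset <- vapply(extra_idx, function(i) {
      sample.int(days_left[i], 1L)
    }, integer(1))
  }
  enc_extra <- tibble(
    patient_id = patient_id[extra_idx],
    date = index_date[extra_idx] + extra_offset,
    enc_type = "outpatient", provider_id = "EXT000",
    provider_type = "Other", prescriber_specialty = "Unknown",
    clinic_type = "Unknown", payer = payer[extra_idx]
  )

  encounters <- bind_rows(
    enc_index |> mutate(.role = "index", .ord = seq_len(n())),
    enc_service |> mutate(.role = "service", .ord = seq_len(n())),
    enc_followup |> mutate(.role = "followup", .ord = seq_len(n())),
    enc_capture |> mutate(.role = "capture", .ord = seq_len(n())),
    enc_extra |> mutate(.role = "extra", .ord = seq_len(n()))
  )
  encounters$encounter_id <- sprintf("E%06d", seq_len(nrow(encounters)))
  index_enc_id <- encounters$encounter_id[encounters$.role == "index"]
  extra_enc_id <- encounters$encounter_id[encounters$.role == "extra"]
  encounters <- encounters |>
    select("encounter_id", "patient_id", "date", "enc_type", "provider_id",
           "provider_type", "prescriber_specialty", "clinic_type", "payer")

  prescriptions <- bind_rows(
    tibble(
      rx_id = truth$rx_id, patient_id = patient_id,
      encounter_id = index_enc_id, rx_date = index_date,
      rxcui = rxcui, drug_name = drug_name
    ),
    tibble(
      rx_id = sprintf("RXX%05d", seq_along(extra_idx)),
      patient_id = patient_id[extra_idx],
      encounter_id = extra_enc_id,
      rx_date = index_date[extra_idx] + extra_offset,
      rxcui = rxcui[extra_idx], drug_name = drug_name[extra_idx]
    )
  )

  # Recorded fills: NDC drawn from the crosswalk entries of the index RxCUI.
  ndc_by_cui <- vocab$index
  fill_ndc <- vapply(rxcui, function(cui) {
    ndcs <- ndc_by_cui[[cui]]
    ndcs[sample.int(length(ndcs), 1L)]
  }, character(1), USE.NAMES = FALSE)
  ndc_names <- setNames(vocab$entries$drug_name, vocab$entries$ndc)

  disp_fill <- tibble(
    patient_id = patient_id[recorded],
    ndc = fill_ndc[recorded],
    fill_date = index_date[recorded] + delay[recorded],
    drug_name = unname(ndc_names[fill_ndc[recorded]])
  )
  disp_decoy <- tibble(
    patient_id = patient_id[decoy],
    ndc = "99999999999",
    fill_date = decoy_date[decoy],
    drug_name = "decoy product"
  )
  prior_ndc <- vapply(seq_len(n), function(i) {
    cui <- sample(names(ndc_by_cui), 1L)
    ndcs <- ndc_by_cui[[cui]]
    ndcs[sample.int(length(ndcs), 1L)]
  }, character(1))
  disp_prior <- tibble(
    patient_id = patient_id[prior_use],
    ndc = prior_ndc[prior_use],
    fill_date = index_date[prior_use] - prior_offset[prior_use],
    drug_name = unname(ndc_names[prior_ndc[prior_use]])
  )
  dispensings <- bind_rows(disp_fill, disp_decoy, disp_prior)
  dispensings$disp_id <- sprintf("D%06d", seq_len(nrow(dispensings)))
  dispensings <- dispensings |>
    select("disp_id", "patient_id", "ndc", "fill_date", "drug_name")

  phq9 <- tibble(
    patient_id = patient_id[phq9_taken],
    date = index_date[phq9_taken] - phq9_offset[phq9_taken],
    score = phq9_score[phq9_taken]
  )

  dx_long <- bind_rows(
    tibble(patient_id, encounter_id = index_enc_id, date = index_date,
           dx = "depression")[dx_depression, ],
    tibble(patient_id, encounter_id = index_enc_id, date = index_date,
           dx = "anxiety")[dx_anxiety, ],
    tibble(patient_id, encounter_id = index_enc_id, date = index_date,
           dx = "adhd")[dx_adhd, ],
    tibble(patient_id, encounter_id = index_enc_id, date = index_date,
           dx = "headache")[dx_headache, ]
  )

  has_capture <- patient_id %in%
    encounters$patient_id[encounters$date >= cwin[1] & encounters$date <= cwin[2]]

  truth <- truth |>
    mutate(
      encounter_id = index_enc_id,
      fill_prob = fill_prob, fill_true = fill_true,
      delay_days = delay, disp_recorded = recorded,
      followup_time = followup_time, followup_event = followup_event,
      prior_use = prior_use, has_capture = has_capture,
      in_cohort = !prior_use & has_capture
    )

  structure(
    list(patients = patients, encounters = encounters,
         prescriptions = prescriptions, dispensings = dispensings,
         phq9 = phq9, diagnoses = dx_long, crosswalk = vocab$entries,
         truth = truth, config = config),
    class = "sim_population"
  )
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(
    "<sim_population> %d patients, %d prescriptions, %d dispensings\n",
    nrow(x$patients), nrow(x$prescriptions), nrow(x$dispensings)
  ))
  invisible(x)
}

sim_population_tables <- c("patients", "encounters", "prescriptions",
                           "dispensings", "phq9", "diagnoses", "crosswalk",
                           "truth")

#' Write a simulated population to delimited text files
#'
#' One CSV per event table plus the truth table, a JSON echo of the
#' configuration, and a plain-text manifest. Round-trips losslessly through
#' [read_population()].
#'
#' @param population A `sim_population`.
#' @param dir Destination directory (created if absent).
#' @return Invisibly, a tibble manifest with one row per written table.
#' @export
write_population <- function(population, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, mode = 2) != 0) {
    abort(sprintf("destination not writable: %s", dir), class = "rxfill_io_error")
  }
  manifest <- purrr::map_dfr(sim_population_tables, function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(population[[name]], path, na = "")
    tibble(table = name, path = path)
  })
  config <- population$config
  config$vocabulary <- NULL  # serialized separately via the crosswalk table
  # named vectors become JSON objects (not arrays) so names survive
  for (field in c("fill_model_coefficients", "followup_coefficients",
                  "extra_rx_rates")) {
    if (!is.null(config[[field]])) config[[field]] <- as.list(config[[field]])
  }
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(sprintf("%s: %s", manifest$table, basename(manifest$path)),
             file.path(dir, "manifest.txt"))
  invisible(manifest)
}

population_col_types <- list(
  patients = readr::cols(
    patient_id = "c", birth_date = "D", sex = "c", race_ethnicity = "c",
    bmi = "d", adi_state_rank = "i"
  ),
  encounters = readr::cols(
    encounter_id = "c", patient_id = "c", date = "D", enc_type = "c",
    provider_id = "c", provider_type = "c", prescriber_specialty = "c",
    clinic_type = "c", payer = "c"
  ),
  prescriptions = readr::cols(
    rx_id = "c", patient_id = "c", encounter_id = "c", rx_date = "D",
    rxcui = "c", drug_name = "c"
  ),
  dispensings = readr::cols(
    disp_id = "c", patient_id = "c", ndc = "c", fill_date = "D",
    drug_name = "c"
  ),
  phq9 = readr::cols(patient_id = "c", date = "D", score = "i"),
  diagnoses = readr::cols(
    patient_id = "c", encounter_id = "c", date = "D", dx = "c"
  ),
  crosswalk = readr::cols(.default = "c"),
  truth = readr::cols(
    patient_id = "c", rx_id = "c", encounter_id = "c", index_date = "D",
    age = "i", sex = "c", race_ethnicity = "c", bmi = "d",
    adi_state_rank = "i", payer = "c", provider_type = "c",
    prescriber_specialty = "c", clinic_type = "c",
    dx_depression = "l", dx_anxiety = "l", dx_adhd = "l", dx_headache = "l",
    ssri = "l", phq9_score = "i", phq9_severity = "c",
    n_rx_at_index = "i", n_rx_in_year = "i",
    wcv_prior_year = "l", wcv_index_year = "l",
    outpatient_prior_year = "l", inpatient_prior_year = "l",
    ed_prior_year = "l", fill_prob = "d", fill_true = "l",
    delay_days = "i", disp_recorded = "l", followup_time = "i",
    followup_event = "l", prior_use = "l", has_capture = "l",
    in_cohort = "l"
  )
)

#' Read a population previously written by [write_population()]
#'
#' @param dir Directory containing the CSV tables and `config.json`.
#' @return A `sim_population`.
#' @export
read_population <- function(dir) {
  tables <- lapply(setNames(nm = sim_population_tables), function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) stop_schema(sprintf("missing table file: %s", path))
    readr::read_csv(path, col_types = population_col_types[[name]],
                    na = c(""), show_col_types = FALSE)
  })
  config_path <- file.path(dir, "config.json")
  config <- NULL
  if (file.exists(config_path)) {
    raw <- jsonlite::read_json(config_path, simplifyVector = TRUE)
    raw$study_window <- as.Date(raw$study_window)
    raw$capture_window <- as.Date(raw$capture_window)
    raw$fill_model_coefficients <- unlist(raw$fill_model_coefficients)
    if (!is.null(raw$followup_coefficients)) {
      raw$followup_coefficients <- unlist(raw$followup_coefficients)
    }
    raw$extra_rx_rates <- unlist(raw$extra_rx_rates)
    config <- do.call(sim_config, raw)
  }
  structure(c(tables, list(config = config)), class = "sim_population")
}
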