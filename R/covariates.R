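#' Categorize a PHQ-9 depression score
#'
#' Standard severity bins: 0-4 nonminimal, 5-9 mild, 10-14 moderate, 15-19
#' moderately severe, 20-27 severe. Missing scores map to `"Not taken"`.
#'
#' @param score Integer vector of PHQ-9 scores in 0-27, `NA` allowed.
#' @return Factor with levels Nonminimal, Mild, Moderate, Moderately severe,
#'   Severe, Not taken.
#' @export
categorize_phq9 <- function(score) {
  bad <- !is.na(score) & (score < 0 | score > 27)
  if (any(bad)) {
    stop_validation(sprintf(
      "PHQ-9 score out of range [0, 27]: %s",
      paste(unique(score[bad]), collapse = ", ")
    ))
  }
  out <- rep("Not taken", length(score))
  idx <- !is.na(score)
  out[idx] <- as.character(cut(
    score[idx],
    breaks = c(-1, 4, 9, 14, 19, 27),
    labels = PHQ9_LEVELS[1:5]
  ))
  factor(out, levels = PHQ9_LEVELS)
}

#' Assemble the contextual covariate table for a cohort
#'
#' Builds one row per cohort member carrying the 22 contextual variables
#' (demographics, index-encounter characteristics, diagnoses at the
#' prescribing visit, SSRI class, PHQ-9 severity, prescription counts, and
#' service-use history flags) together with the fill label from linkage.
#'
#' @param cohort Index events from [identify_new_users()] /
#'   [apply_completeness_filter()].
#' @param patients,encounters,diagnoses,phq9,prescriptions Event tables.
#' @param links A `linkage_result` (or its `links` tibble) supplying
#'   `filled_within_cutoff` per `rx_id`.
#' @param vocab A `medication_vocabulary` (supplies the SSRI class and the
#'   psychotropic RxCUI set for prescription counts).
#' @param phq9_lookback_days Days before (and including) the index date in
#'   which a PHQ-9 counts (default 14, i.e. the two weeks prior).
#' @return Tibble: `patient_id`, `fill_status`, then the 22 covariates with
#'   typed columns (factors carry their full level sets).
#' @export
build_covariate_table <- function(cohort, patients, encounters, diagnoses,
                                  phq9, prescriptions, links, vocab,
                                  phq9_lookback_days = 14L) {
  if (inherits(links, "linkage_result")) links <- links$links
  check_columns(links, c("rx_id", "days_to_fill", "filled_within_cutoff"),
                "links")

  unresolved <- setdiff(cohort$patient_id, patients$patient_id)
  if (length(unresolved) > 0) {
    stop_validation(sprintf("cohort references unknown patient(s): %s",
                            unresolved[1]))
  }
  if (!all(cohort$rx_id %in% links$rx_id)) {
    stop_validation("cohort references rx_id(s) absent from the links table")
  }

  psych_cuis <- names(vocab$index)
  classes <- vocab_classes(vocab)

  base <- cohort |>
    left_join(select(links, "rx_id", "filled_within_cutoff"), by = "rx_id") |>
    rename(fill_status = "filled_within_cutoff") |>
    left_join(patients, by = "patient_id") |>
    left_join(
      select(encounters, "encounter_id", "provider_type",
             "prescriber_specialty", "clinic_type", "payer"),
      by = "encounter_id"
    ) |>
    mutate(age = age_at(.data$birth_date, .data$index_date))

  # Diagnoses recorded at the prescribing encounter.
  dx_at_index <- diagnoses |>
    semi_join(cohort, by = "encounter_id") |>
    distinct(.data$encounter_id, .data$dx) |>
    mutate(flag = TRUE) |>
    tidyr::pivot_wider(names_from = "dx", values_from = "flag",
                       values_fill = FALSE)
  for (dx in c("depression", "anxiety", "adhd", "headache")) {
    if (!dx %in% names(dx_at_index)) dx_at_index[[dx]] <- FALSE
  }
  base <- base |>
    left_join(dx_at_index, by = "encounter_id") |>
    mutate(across(c("depression", "anxiety", "adhd", "headache"),
                  ~ ifelse(is.na(.x), FALSE, .x)))

  # SSRI class of the index prescription.
  index_rx <- prescriptions |>
    semi_join(cohort, by = "rx_id") |>
    select("rx_id", "rxcui")
  base <- base |>
    left_join(index_rx, by = "rx_id") |>
    mutate(ssri = unname(!is.na(classes[.data$rxcui]) &
                           classes[.data$rxcui] == "SSRI"))

  # Most recent PHQ-9 in the lookback window (ties on date: highest score).
  phq_window <- phq9 |>
    inner_join(select(cohort, "patient_id", "index_date"), by = "patient_id") |>
    filter(.data$date >= .data$index_date - phq9_lookback_days,
           .data$date <= .data$index_date) |>
    arrange(.data$patient_id, desc(.data$date), desc(.data$score)) |>
    distinct(.data$patient_id, .keep_all = TRUE) |>
    select("patient_id", phq9_recent = "score")
  base <- base |>
    left_join(phq_window, by = "patient_id") |>
    mutate(phq9_severity = categorize_phq9(.data$phq9_recent))

  # Prescription counts (psychotropic only).
  psych_rx <- prescriptions |> filter(.data$rxcui %in% psych_cuis)
  n_at_index <- psych_rx |>
    count(.data$encounter_id, name = "n_rx_at_index")
  n_in_year <- psych_rx |>
    inner_join(select(cohort, "patient_id", "index_date"), by = "patient_id") |>
    filter(year_of(.data$rx_date) == year_of(.data$index_date)) |>
    count(.data$patient_id, name = "n_rx_in_year")
  base <- base |>
    left_join(n_at_index, by = "encounter_id") |>
    left_join(n_in_year, by = "patient_id") |>
    mutate(n_rx_at_index = coalesce(as.integer(.data$n_rx_at_index), 1L),
           n_rx_in_year = coalesce(as.integer(.data$n_rx_in_year), 1L))

  # Service-use flags over the prior and index calendar years.
  enc <- encounters |>
    inner_join(select(cohort, "patient_id", "index_date"), by = "patient_id",
               relationship = "many-to-many") |>
    mutate(
      enc_year = year_of(.data$date),
      index_year = year_of(.data$index_date)
    )
  flag_of <- function(enc, type, offset) {
    enc |>
      filter(.data$enc_type == type,
             .data$enc_year == .data$index_year - offset) |>
      distinct(.data$patient_id) |>
      mutate(flag = TRUE)
  }
  base <- base |>
    left_join(flag_of(enc, "well_child", 1L), by = "patient_id") |>
    rename(wcv_prior_year = "flag") |>
    left_join(flag_of(enc, "well_child", 0L), by = "patient_id") |>
    rename(wcv_index_year = "flag") |>
    left_join(flag_of(enc, "outpatient", 1L), by = "patient_id") |>
    rename(outpatient_prior_year = "flag") |>
    left_join(flag_of(enc, "inpatient", 1L), by = "patient_id") |>
    rename(inpatient_prior_year = "flag") |>
    left_join(flag_of(enc, "ed", 1L), by = "patient_id") |>
    rename(ed_prior_year = "flag") |>
    mutate(across(c("wcv_prior_year", "wcv_index_year",
                    "outpatient_prior_year", "inpatient_prior_year",
                    "ed_prior_year"),
                  ~ !is.na(.x)))

  out <- base |>
    transmute(
      patient_id = .data$patient_id,
      fill_status = .data$fill_status,
      age = .data$age,
      sex = factor(.data$sex, levels = SEX_LEVELS),
      race_ethnicity = factor(.data$race_ethnicity, levels = RACE_LEVELS),
      bmi = .data$bmi,
      adi_state_rank = .data$adi_state_rank,
      payer = factor(.data$payer, levels = PAYER_LEVELS),
      provider_type = factor(.data$provider_type, levels = PROVIDER_LEVELS),
      prescriber_specialty = factor(.data$prescriber_specialty,
                                    levels = SPECIALTY_LEVELS),
      clinic_type = factor(.data$clinic_type, levels = CLINIC_LEVELS),
      dx_depression = .data$depression,
      dx_anxiety = .data$anxiety,
      dx_adhd = .data$adhd,
      dx_headache = .data$headache,
      ssri = .data$ssri,
      phq9_severity = .data$phq9_severity,
      n_rx_at_index = .data$n_rx_at_index,
      n_rx_in_year = .data$n_rx_in_year,
      wcv_prior_year = .data$wcv_prior_year,
      wcv_index_year = .data$wcv_index_year,
      outpatient_prior_year = .data$outpatient_prior_year,
      inpatient_prior_year = .data$inpatient_prior_year,
      ed_prior_year = .data$ed_prior_year
    )
  stopifnot(nrow(out) == nrow(cohort))
  out
}
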