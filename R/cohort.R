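#' Identify new users of psychotropic medication
#'
#' Implements the new-user (incident-user) design: for each patient the
#' earliest in-window psychotropic prescription written at an outpatient
#' encounter is the candidate index event. The patient is excluded when any
#' psychotropic prescription or dispensing exists during the washout interval
#' `[index_date - washout_days, index_date)`, or when they are 18 or older at
#' the index date.
#'
#' @param prescriptions,dispensings,patients,encounters Event tables as
#'   produced by [generate_population()] (or read from an extraction with the
#'   same schema).
#' @param vocab A `medication_vocabulary` defining which RxCUIs/NDCs count as
#'   psychotropic.
#' @param study_window Length-2 `Date` vector bounding eligible index dates.
#' @param washout_days Lookback in days (default 365, i.e. 12 months).
#' @return Tibble of index events (`patient_id`, `rx_id`, `encounter_id`,
#'   `index_date`, `age_at_index`, `prescriber_id`), at most one row per
#'   patient, with an `attrition` attribute logging counts per filter stage.
#' @export
identify_new_users <- function(prescriptions, dispensings, patients,
                               encounters, vocab, study_window,
                               washout_days = 365L) {
  if (!is_pos_int(washout_days)) {
    stop_config("`washout_days` must be a positive integer", "washout_days")
  }
  check_columns(patients, c("patient_id", "birth_date"), "patients")
  check_columns(encounters, c("encounter_id", "enc_type", "provider_id"),
                "encounters")

  psych_cuis <- names(vocab$index)
  psych_ndcs <- vocab_ndcs(vocab)

  rx <- prescriptions |>
    filter(.data$rxcui %in% psych_cuis)
  missing_patients <- setdiff(rx$patient_id, patients$patient_id)
  if (length(missing_patients) > 0) {
    stop_validation(sprintf(
      "prescriptions reference %d patient(s) absent from the patients table (e.g. %s)",
      length(missing_patients), missing_patients[1]
    ))
  }

  candidates <- rx |>
    inner_join(select(encounters, "encounter_id", "enc_type", "provider_id"),
               by = "encounter_id") |>
    filter(.data$enc_type == "outpatient",
           .data$rx_date >= study_window[1],
           .data$rx_date <= study_window[2]) |>
    arrange(.data$rx_date, .data$rx_id) |>
    distinct(.data$patient_id, .keep_all = TRUE) |>
    rename(index_date = "rx_date", prescriber_id = "provider_id") |>
    select("patient_id", "rx_id", "encounter_id", "index_date",
           "prescriber_id")
  n_candidates <- nrow(candidates)

  # Washout: any psychotropic prescription or fill in the lookback interval.
  psych_disp <- dispensings |>
    mutate(ndc_norm = normalize_ndc(.data$ndc)) |>
    filter(.data$ndc_norm %in% psych_ndcs)
  history <- bind_rows(
    rx |> select("patient_id", event_date = "rx_date"),
    psych_disp |> select("patient_id", event_date = "fill_date")
  )
  washed <- candidates |>
    left_join(history, by = "patient_id", relationship = "many-to-many") |>
    group_by(.data$patient_id) |>
    summarise(prior_use = any(
      .data$event_date >= .data$index_date[1] - washout_days &
        .data$event_date < .data$index_date[1], na.rm = TRUE
    ), .groups = "drop")
  candidates <- candidates |>
    left_join(washed, by = "patient_id") |>
    filter(!.data$prior_use) |>
    select(-"prior_use")
  n_washout <- nrow(candidates)

  candidates <- candidates |>
    inner_join(select(patients, "patient_id", "birth_date"),
               by = "patient_id") |>
    mutate(age_at_index = age_at(.data$birth_date, .data$index_date)) |>
    filter(.data$age_at_index < 18L) |>
    select(-"birth_date")
  n_age <- nrow(candidates)

  attr(candidates, "attrition") <- tibble(
    stage = c("index candidates", "washout", "age < 18"),
    n_before = c(n_candidates, n_candidates, n_washout),
    n_after = c(n_candidates, n_washout, n_age)
  )
  candidates
}

#' Restrict a cohort to patients with complete dispensing capture
#'
#' Dispensing feeds are only reconciled into the record for patients seen
#' again by the health system, so the cohort is limited to patients with at
#' least one encounter of any type during the capture window.
#'
#' @param index_events Output of [identify_new_users()].
#' @param encounters Encounters table.
#' @param capture_window Length-2 `Date` vector (typically the year after the
#'   study window).
#' @return Filtered index events; the `attrition` attribute is extended.
#' @export
apply_completeness_filter <- function(index_events, encounters,
                                      capture_window) {
  if (!inherits(capture_window, "Date") || length(capture_window) != 2) {
    stop_config("`capture_window` must be a length-2 Date vector",
                "capture_window")
  }
  check_columns(encounters, c("patient_id", "date"), "encounters")
  seen <- unique(encounters$patient_id[
    encounters$date >= capture_window[1] & encounters$date <= capture_window[2]
  ])
  n_before <- nrow(index_events)
  out <- index_events |> filter(.data$patient_id %in% seen)
  prev <- attr(index_events, "attrition")
  attr(out, "attrition") <- bind_rows(
    prev,
    tibble(stage = "capture-window encounter", n_before = n_before,
           n_after = nrow(out))
  )
  out
}

#' CONSORT-style attrition log of a cohort
#'
#' @param index_events A cohort tibble carrying an `attrition` attribute.
#' @return Tibble with `stage`, `n_before`, `n_after`.
#' @export
attrition_log <- function(index_events) {
  log <- attr(index_events, "attrition")
  if (is.null(log)) stop_domain("no attrition log attached to this cohort")
  log
}
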