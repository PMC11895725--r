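test_that("PHQ-9 severity bins follow the standard cut points", {
  # boundary map across all five bins plus missing
  scores <- c(0, 4, 5, 9, 10, 14, 15, 19, 20, 27, NA)
  expected <- c("Nonminimal", "Nonminimal", "Mild", "Mild", "Moderate",
                "Moderate", "Moderately severe", "Moderately severe",
                "Severe", "Severe", "Not taken")
  expect_equal(as.character(categorize_phq9(scores)), expected)
  expect_s3_class(categorize_phq9(10), "factor")
  expect_error(categorize_phq9(28), class = "rxfill_validation_error")
  expect_error(categorize_phq9(-1), class = "rxfill_validation_error")
})

covariate_fixture <- function(phq_offset_days = 10, phq_score = 16) {
  vocab <- tiny_vocab()
  index_date <- as.Date("2021-06-10")
  patients <- tibble::tibble(
    patient_id = "p1", birth_date = as.Date("2007-02-01"), sex = "Female",
    race_ethnicity = "NH Black", bmi = NA_real_, adi_state_rank = 4
  )
  encounters <- tibble::tibble(
    encounter_id = c("e1", "e2", "e3"),
    patient_id = "p1",
    date = c(index_date, as.Date("2020-04-01"), as.Date("2022-03-01")),
    enc_type = c("outpatient", "well_child", "outpatient"),
    provider_id = c("prv1", "ext", "ext"),
    provider_type = c("Physician", "Other", "Other"),
    prescriber_specialty = c("Psychiatry", "Unknown", "Unknown"),
    clinic_type = c("Behavioral health", "Unknown", "Unknown"),
    payer = "Public"
  )
  prescriptions <- tibble::tibble(
    rx_id = c("r1", "r2"), patient_id = "p1", encounter_id = c("e1", "e1"),
    rx_date = index_date, rxcui = c("A", "B"),
    drug_name = c("sertraline 25mg tablet", "fluoxetine 10mg capsule")
  )
  diagnoses <- tibble::tibble(
    patient_id = "p1", encounter_id = "e1", date = index_date,
    dx = c("anxiety", "headache")
  )
  phq9 <- tibble::tibble(patient_id = "p1",
                         date = index_date - phq_offset_days,
                         score = phq_score)
  cohort <- tibble::tibble(
    patient_id = "p1", rx_id = "r1", encounter_id = "e1",
    index_date = index_date, prescriber_id = "prv1", age_at_index = 14L
  )
  links <- tibble::tibble(rx_id = c("r1", "r2"), days_to_fill = c(3L, NA),
                          filled_within_cutoff = c(TRUE, FALSE))
  list(vocab = vocab, patients = patients, encounters = encounters,
       prescriptions = prescriptions, diagnoses = diagnoses, phq9 = phq9,
       cohort = cohort, links = links)
}

test_that("the covariate row assembles every contextual variable", {
  fx <- covariate_fixture()
  row <- build_covariate_table(fx$cohort, fx$patients, fx$encounters,
                               fx$diagnoses, fx$phq9, fx$prescriptions,
                               fx$links, fx$vocab)
  expect_equal(nrow(row), 1)
  expect_true(all(COVARIATE_NAMES %in% names(row)))
  expect_true(row$fill_status)
  expect_equal(row$age, 14L)
  expect_equal(as.character(row$prescriber_specialty), "Psychiatry")
  expect_true(row$dx_anxiety)
  expect_true(row$dx_headache)
  expect_false(row$dx_depression)
  expect_true(row$ssri)
  expect_true(is.na(row$bmi))
  # PHQ-9 score 16 taken 10 days pre-index: inside the 2-week window
  expect_equal(as.character(row$phq9_severity), "Moderately severe")
  # both index-encounter prescriptions are psychotropic
  expect_equal(row$n_rx_at_index, 2L)
  expect_equal(row$n_rx_in_year, 2L)
  expect_true(row$wcv_prior_year)
  expect_false(row$wcv_index_year)
  expect_false(row$outpatient_prior_year)
  expect_false(row$ed_prior_year)
})

test_that("a PHQ-9 outside the lookback window maps to Not taken", {
  fx <- covariate_fixture(phq_offset_days = 20)
  row <- build_covariate_table(fx$cohort, fx$patients, fx$encounters,
                               fx$diagnoses, fx$phq9, fx$prescriptions,
                               fx$links, fx$vocab)
  expect_equal(as.character(row$phq9_severity), "Not taken")
})

test_that("members without prior-year encounters have all service flags false", {
  fx <- covariate_fixture()
  fx$encounters <- fx$encounters[fx$encounters$encounter_id != "e2", ]
  row <- build_covariate_table(fx$cohort, fx$patients, fx$encounters,
                               fx$diagnoses, fx$phq9, fx$prescriptions,
                               fx$links, fx$vocab)
  expect_false(any(row$wcv_prior_year, row$outpatient_prior_year,
                   row$inpatient_prior_year, row$ed_prior_year))
})

test_that("unresolvable references raise referential-integrity errors", {
  fx <- covariate_fixture()
  fx$patients$patient_id <- "someone-else"
  expect_error(
    build_covariate_table(fx$cohort, fx$patients, fx$encounters,
                          fx$diagnoses, fx$phq9, fx$prescriptions,
                          fx$links, fx$vocab),
    class = "rxfill_validation_error"
  )
})

test_that("covariates recovered from synthetic tables equal the generator truth", {
  pop <- generate_population(noise_free_config(n = 300, seed = 23))
  vocab <- load_crosswalk(default_crosswalk_path())
  links <- match_fills(pop$prescriptions, pop$dispensings, vocab)
  cohort <- identify_new_users(pop$prescriptions, pop$dispensings,
                               pop$patients, pop$encounters, vocab,
                               pop$config$study_window) |>
    apply_completeness_filter(pop$encounters, pop$config$capture_window)
  rows <- build_covariate_table(cohort, pop$patients, pop$encounters,
                                pop$diagnoses, pop$phq9, pop$prescriptions,
                                links, vocab)
  truth <- pop$truth[match(rows$patient_id, pop$truth$patient_id), ]
  expect_equal(rows$age, truth$age)
  expect_equal(as.character(rows$sex), truth$sex)
  expect_equal(as.character(rows$race_ethnicity), truth$race_ethnicity)
  expect_equal(rows$bmi, truth$bmi)
  expect_equal(rows$adi_state_rank, truth$adi_state_rank)
  expect_equal(as.character(rows$payer), truth$payer)
  expect_equal(as.character(rows$provider_type), truth$provider_type)
  expect_equal(as.character(rows$prescriber_specialty),
               truth$prescriber_specialty)
  expect_equal(as.character(rows$clinic_type), truth$clinic_type)
  expect_equal(rows$dx_depression, truth$dx_depression)
  expect_equal(rows$dx_anxiety, truth$dx_anxiety)
  expect_equal(rows$dx_adhd, truth$dx_adhd)
  expect_equal(rows$dx_headache, truth$dx_headache)
  expect_equal(rows$ssri, truth$ssri)
  expect_equal(as.character(rows$phq9_severity), truth$phq9_severity)
  expect_equal(rows$n_rx_at_index, truth$n_rx_at_index)
  expect_equal(rows$n_rx_in_year, truth$n_rx_in_year)
  expect_equal(rows$wcv_prior_year, truth$wcv_prior_year)
  expect_equal(rows$wcv_index_year, truth$wcv_index_year)
  expect_equal(rows$outpatient_prior_year, truth$outpatient_prior_year)
  expect_equal(rows$inpatient_prior_year, truth$inpatient_prior_year)
  expect_equal(rows$ed_prior_year, truth$ed_prior_year)
  # and the recovered fill label equals the true fill-within-cutoff status
  expect_equal(rows$fill_status,
               truth$fill_true & !is.na(truth$delay_days) &
                 truth$delay_days <= 30)
})
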