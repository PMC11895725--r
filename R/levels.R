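# Canonical category levels shared by the generator and the covariate builder.

SEX_LEVELS       <- c("Female", "Male")
RACE_LEVELS      <- c("Hispanic", "NH Asian", "NH Black", "NH White", "Other")
PAYER_LEVELS     <- c("Public", "Private", "Self-pay")
PROVIDER_LEVELS  <- c("Physician", "Other")
SPECIALTY_LEVELS <- c("Primary care", "Psychiatry", "Other", "Unknown")
CLINIC_LEVELS    <- c("Primary care", "Behavioral health", "Other", "Unknown")
PHQ9_LEVELS      <- c("Nonminimal", "Mild", "Moderate", "Moderately severe",
                      "Severe", "Not taken")
ENCOUNTER_TYPES  <- c("outpatient", "inpatient", "ed", "well_child")

# Names of the 22 contextual covariates, in reporting order.
COVARIATE_NAMES <- c(
  "age", "sex", "race_ethnicity", "bmi", "adi_state_rank", "payer",
  "provider_type", "prescriber_specialty", "clinic_type",
  "dx_depression", "dx_anxiety", "dx_adhd", "dx_headache", "ssri",
  "phq9_severity", "n_rx_at_index", "n_rx_in_year",
  "wcv_prior_year", "wcv_index_year",
  "outpatient_prior_year", "inpatient_prior_year", "ed_prior_year"
)
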