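test_that("generation is deterministic given the config seed", {
  cfg <- sim_config(n_patients = 120, seed = 99)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  for (name in c("patients", "encounters", "prescriptions", "dispensings",
                 "phq9", "diagnoses", "truth")) {
    expect_identical(a[[name]], b[[name]], label = name)
  }
  c <- generate_population(sim_config(n_patients = 120, seed = 100))
  expect_false(identical(a$truth$fill_true, c$truth$fill_true))
})

test_that("invalid config fields raise configuration errors naming the field", {
  expect_error(sim_config(n_patients = -5), class = "rxfill_config_error")
  expect_error(sim_config(coverage_miss_rate = 1.2),
               class = "rxfill_config_error")
  err <- tryCatch(sim_config(decoy_dispensing_rate = -0.1),
                  error = function(e) e)
  expect_equal(err$field, "decoy_dispensing_rate")
  # unknown covariate in the coefficient map surfaces at generation time
  cfg <- sim_config(n_patients = 20,
                    fill_model_coefficients = c(intercept = 0, bogus = 1))
  expect_error(generate_population(cfg), class = "rxfill_config_error")
})

test_that("degenerate no-noise config yields one matchable dispensing per prescription", {
  cfg <- sim_config(
    n_patients = 80, seed = 5, nonfill_rate_target = 0,
    coverage_miss_rate = 0, decoy_dispensing_rate = 0, prior_use_rate = 0,
    extra_rx_rates = c(filled = 0, not_filled = 0)
  )
  pop <- generate_population(cfg)
  expect_equal(nrow(pop$prescriptions), 80)
  expect_equal(nrow(pop$dispensings), 80)
  expect_true(all(pop$truth$fill_true))
  vocab <- load_crosswalk(default_crosswalk_path())
  links <- match_fills(pop$prescriptions, pop$dispensings, vocab)
  expect_true(all(!is.na(links$links$days_to_fill)))
})

test_that("with zero coefficients the empirical fill rate matches the intercept", {
  p <- 0.778
  cfg <- sim_config(
    n_patients = 5000, seed = 11,
    fill_model_coefficients = c(intercept = qlogis(p)),
    nonfill_rate_target = NULL
  )
  pop <- generate_population(cfg)
  k <- sum(pop$truth$fill_true)
  # oracle: exact binomial 99% CI around the realized count must contain p
  ci <- binom.test(k, 5000, conf.level = 0.99)$conf.int
  expect_gt(p, ci[1])
  expect_lt(p, ci[2])
})

test_that("intercept calibration hits the configured nonfill rate", {
  cfg <- sim_config(n_patients = 5000, seed = 21, nonfill_rate_target = 0.222)
  pop <- generate_population(cfg)
  expect_equal(mean(pop$truth$fill_prob), 1 - 0.222, tolerance = 1e-6)
})

test_that("fill delays follow the configured same-day/weekly mixture", {
  cfg <- sim_config(n_patients = 2000, seed = 33)
  pop <- generate_population(cfg)
  delays <- pop$truth$delay_days[pop$truth$fill_true]
  n <- length(delays)
  p0 <- mean(delays == 0)
  p7 <- mean(delays <= 7)
  # three Monte-Carlo standard errors around the configured mixture masses
  expect_lt(abs(p0 - 0.812), 3 * sqrt(0.812 * 0.188 / n))
  expect_lt(abs(p7 - 0.913), 3 * sqrt(0.913 * 0.087 / n))
})

test_that("event tables are internally consistent", {
  pop <- generate_population(sim_config(n_patients = 150, seed = 8))
  expect_true(all(pop$prescriptions$patient_id %in% pop$patients$patient_id))
  expect_true(all(pop$prescriptions$encounter_id %in%
                    pop$encounters$encounter_id))
  # recorded (non-decoy) fills never precede their prescription
  fills <- dplyr::inner_join(
    pop$dispensings[pop$dispensings$drug_name != "decoy product", ],
    pop$truth[, c("patient_id", "index_date")],
    by = "patient_id"
  )
  prior <- pop$truth$patient_id[pop$truth$prior_use]
  on_index <- fills[!(fills$patient_id %in% prior), ]
  expect_true(all(on_index$fill_date >= on_index$index_date))
  expect_equal(nrow(pop$truth),
               sum(grepl("^RX\\d", pop$prescriptions$rx_id)))
})

test_that("covariates with nonzero fill coefficients separate the groups", {
  pop <- generate_population(sim_config(n_patients = 2500, seed = 13))
  tr <- pop$truth
  g1 <- tr[tr$fill_true, ]
  g2 <- tr[!tr$fill_true, ]
  # anxiety carries the largest default coefficient
  expect_gt(smd_binary(sum(g1$dx_anxiety), nrow(g1),
                       sum(g2$dx_anxiety), nrow(g2)), 0.10)
  expect_gt(smd_binary(sum(g1$wcv_prior_year), nrow(g1),
                       sum(g2$wcv_prior_year), nrow(g2)), 0.10)
  # a covariate with zero coefficient stays balanced at this n
  expect_lt(smd_binary(sum(g1$dx_adhd), nrow(g1),
                       sum(g2$dx_adhd), nrow(g2)), 0.10)
})

test_that("populations round-trip losslessly through write/read", {
  pop <- generate_population(sim_config(n_patients = 60, seed = 2))
  dir <- withr::local_tempdir()
  manifest <- write_population(pop, dir)
  expect_equal(nrow(manifest), 8)  # one path per table
  back <- read_population(dir)
  for (name in c("patients", "encounters", "prescriptions", "dispensings",
                 "phq9", "diagnoses", "crosswalk", "truth")) {
    expect_equal(as.data.frame(back[[name]]), as.data.frame(pop[[name]]),
                 label = name)
  }
})

test_that("an empty population writes headers-only files", {
  pop <- generate_population(sim_config(n_patients = 5, seed = 2))
  for (name in c("patients", "encounters", "prescriptions", "dispensings",
                 "phq9", "diagnoses", "truth")) {
    pop[[name]] <- pop[[name]][0, ]
  }
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  lines <- readLines(file.path(dir, "patients.csv"))
  expect_length(lines, 1)  # header only
  back <- read_population(dir)
  expect_equal(nrow(back$patients), 0)
  expect_named(back$patients, names(pop$patients))
})

test_that("unwritable destination raises an I/O error", {
  pop <- generate_population(sim_config(n_patients = 5, seed = 2))
  blocker <- withr::local_tempfile(lines = "not a directory")
  expect_error(write_population(pop, file.path(blocker, "sub")),
               class = "rxfill_io_error")
})
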