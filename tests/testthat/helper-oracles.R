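# Independent oracles and in-code fixtures shared across test files.

# Build a small vocabulary by writing a temporary crosswalk CSV through the
# public loader (also exercises NDC normalization on load).
make_vocab <- function(entries) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(entries, path)
  load_crosswalk(path)
}

tiny_vocab <- function() {
  make_vocab(tibble::tibble(
    rxcui = c("A", "A", "B", "B"),
    ndc = c("11111-1111-11", "11111-1111-12", "22222-2222-21", "22222-2222-22"),
    drug_name = c("sertraline 25mg tablet", "sertraline 50mg tablet",
                  "fluoxetine 10mg capsule", "fluoxetine 20mg capsule"),
    drug_class = c("SSRI", "SSRI", "SSRI", "SSRI")
  ))
}

# Brute-force product-limit estimator: recompute survival step by step from
# first principles, emitting one row per unique observed time.
km_oracle <- function(times, events, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(times))
  uts <- sort(unique(times))
  surv <- 1
  out <- lapply(uts, function(t) {
    n_risk <- sum(weights[times >= t])
    d <- sum(weights[times == t & events])
    if (d > 0) surv <<- surv * (1 - d / n_risk)
    data.frame(time = t, n_risk = n_risk, n_event = d, survival = surv)
  })
  do.call(rbind, out)
}

# Exhaustive earliest-first one-to-one assignment oracle. Enumerates every
# feasible complete assignment (each prescription either takes an unused
# compatible dispensing or stays unmatched) and returns the one whose
# per-prescription (fill_date, disp_id) sequence, in ascending
# (rx_date, rx_id) order, is lexicographically smallest (unmatched sorts
# last). Only usable on tiny instances.
oracle_match <- function(prescriptions, dispensings, vocab,
                         search_horizon_days = 365L) {
  rx <- prescriptions[order(prescriptions$rx_date, prescriptions$rx_id), ]
  disp <- dispensings
  disp$ndc_norm <- normalize_ndc(disp$ndc)
  n <- nrow(rx)
  cand <- lapply(seq_len(n), function(i) {
    ok <- ndcs_for_rxcui(vocab, rx$rxcui[i], rx$drug_name[i])
    which(
      disp$patient_id == rx$patient_id[i] &
        !is.na(disp$ndc_norm) & disp$ndc_norm %in% ok &
        disp$fill_date >= rx$rx_date[i] &
        as.integer(disp$fill_date - rx$rx_date[i]) <= search_horizon_days
    )
  })

  best <- NULL
  # keys: numeric fill dates (Inf = unmatched) primary, disp_id tiebreak
  better <- function(dates_a, ids_a, dates_b, ids_b) {
    for (i in seq_along(dates_a)) {
      if (dates_a[i] != dates_b[i]) return(dates_a[i] < dates_b[i])
      if (ids_a[i] != ids_b[i]) return(ids_a[i] < ids_b[i])
    }
    FALSE
  }
  recurse <- function(i, used, dates, ids) {
    if (i > n) {
      if (is.null(best) || better(dates, ids, best$dates, best$ids)) {
        best <<- list(dates = dates, ids = ids)
      }
      return(invisible())
    }
    options <- setdiff(cand[[i]], used)
    for (j in options) {
      recurse(i + 1, c(used, j),
              c(dates, as.numeric(disp$fill_date[j])),
              c(ids, disp$disp_id[j]))
    }
    recurse(i + 1, used, c(dates, Inf), c(ids, "~unmatched~"))
  }
  recurse(1L, integer(0), numeric(0), character(0))
  days <- rep(NA_integer_, n)
  finite <- is.finite(best$dates)
  days[finite] <- as.integer(best$dates[finite] -
                               as.numeric(rx$rx_date[finite]))
  tibble::tibble(
    rx_id = rx$rx_id,
    disp_id = ifelse(best$ids == "~unmatched~", NA_character_, best$ids),
    days_to_fill = days
  )
}

# Random small linkage instance over the tiny vocabulary.
random_linkage_instance <- function(seed) {
  set.seed(seed)
  n_rx <- sample(2:6, 1)
  n_disp <- sample(2:6, 1)
  patients <- c("p1", "p2")
  cuis <- c("A", "B")
  names_of <- c(A = "sertraline 25mg tablet", B = "fluoxetine 10mg capsule")
  ndcs <- c("11111-1111-11", "11111-1111-12", "22222-2222-21",
            "22222-2222-22", "33333-3333-33")  # last one unknown to the vocab
  epoch <- as.Date("2021-01-01")
  rx <- tibble::tibble(
    rx_id = sprintf("rx%02d", seq_len(n_rx)),
    patient_id = sample(patients, n_rx, TRUE),
    encounter_id = sprintf("e%02d", seq_len(n_rx)),
    rx_date = epoch + sample(0:20, n_rx, TRUE),
    rxcui = sample(cuis, n_rx, TRUE)
  )
  rx$drug_name <- unname(names_of[rx$rxcui])
  disp <- tibble::tibble(
    disp_id = sprintf("d%02d", seq_len(n_disp)),
    patient_id = sample(patients, n_disp, TRUE),
    ndc = sample(ndcs, n_disp, TRUE),
    fill_date = epoch + sample(0:30, n_disp, TRUE),
    drug_name = "whatever"
  )
  list(prescriptions = rx, dispensings = disp)
}

# Noise-free simulation config used by truth-recovery tests.
noise_free_config <- function(n = 200, seed = 1) {
  sim_config(
    n_patients = n, seed = seed,
    coverage_miss_rate = 0, decoy_dispensing_rate = 0
  )
}
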