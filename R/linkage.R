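#' Match prescriptions to dispensing records
#'
#' Links each prescription to at most one dispensing record. Prescriptions are
#' processed in ascending (`rx_date`, `rx_id`) order; for each one, candidate
#' dispensings are those of the same patient whose (normalized) NDC is
#' compatible with the prescription's RxCUI (validated against the drug name,
#' see [ndcs_for_rxcui()]), whose fill date falls on or after the prescription
#' date and within `search_horizon_days`, and which have not already been
#' assigned to an earlier prescription. The candidate with the earliest fill
#' date wins (ties broken by smallest `disp_id`), so no dispensing is ever
#' matched to more than one prescription.
#'
#' @param prescriptions Tibble with columns `rx_id`, `patient_id`,
#'   `encounter_id`, `rx_date`, `rxcui`, `drug_name`.
#' @param dispensings Tibble with columns `disp_id`, `patient_id`, `ndc`,
#'   `fill_date`, `drug_name`.
#' @param vocab A `medication_vocabulary`.
#' @param search_horizon_days Maximum days after prescribing that a fill may
#'   be considered a match (default 365, spanning the capture year).
#' @param cutoff_days Day cutoff used to label `filled_within_cutoff`
#'   (default 30); relabel later with [apply_fill_cutoff()].
#' @return A `linkage_result`: list with `links` (one row per prescription:
#'   `rx_id`, `patient_id`, `rx_date`, `disp_id`, `days_to_fill`,
#'   `filled_within_cutoff`), `unmatched_dispensings`, `cutoff_days`, and
#'   `diagnostics` (candidate/rejection/unknown-RxCUI counts).
#' @export
match_fills <- function(prescriptions, dispensings, vocab,
                        search_horizon_days = 365L, cutoff_days = 30L) {
  check_columns(prescriptions,
                c("rx_id", "patient_id", "rx_date", "rxcui", "drug_name"),
                "prescriptions")
  check_columns(dispensings,
                c("disp_id", "patient_id", "ndc", "fill_date"),
                "dispensings")
  if (!is_pos_int(search_horizon_days)) {
    stop_config("`search_horizon_days` must be a positive integer",
                "search_horizon_days")
  }
  if (anyDuplicated(prescriptions$rx_id)) {
    stop_validation("duplicate rx_id in prescriptions")
  }
  if (anyDuplicated(dispensings$disp_id)) {
    stop_validation("duplicate disp_id in dispensings")
  }

  rx <- prescriptions |>
    arrange(.data$rx_date, .data$rx_id)
  disp <- dispensings |>
    mutate(ndc_norm = normalize_ndc(.data$ndc))

  disp_by_patient <- split(seq_len(nrow(disp)), disp$patient_id)
  assigned <- logical(nrow(disp))

  n_rx <- nrow(rx)
  out_disp <- rep(NA_character_, n_rx)
  out_days <- rep(NA_integer_, n_rx)
  n_candidates <- 0L
  n_unknown_rxcui <- 0L
  n_name_rejections <- 0L

  # NDC sets are memoized per (rxcui, ingredient token) pair.
  ndc_cache <- new.env(parent = emptyenv())
  lookup_ndcs <- function(cui, name) {
    key <- paste0(cui, "\r", ingredient_token(name %||% ""))
    hit <- ndc_cache[[key]]
    if (!is.null(hit)) return(hit)
    value <- ndcs_for_rxcui(vocab, cui, name)
    ndc_cache[[key]] <- value
    value
  }

  for (i in seq_len(n_rx)) {
    ok_ndcs <- lookup_ndcs(rx$rxcui[i], rx$drug_name[i])
    if (length(ok_ndcs) == 0) {
      if (is.null(vocab$index[[as.character(rx$rxcui[i])]])) {
        n_unknown_rxcui <- n_unknown_rxcui + 1L
      } else {
        n_name_rejections <- n_name_rejections + 1L
      }
      next
    }
    cand <- disp_by_patient[[rx$patient_id[i]]]
    if (is.null(cand)) next
    cand <- cand[!assigned[cand]]
    if (length(cand) == 0) next
    gap <- as.integer(disp$fill_date[cand] - rx$rx_date[i])
    keep <- !is.na(disp$ndc_norm[cand]) &
      disp$ndc_norm[cand] %in% ok_ndcs &
      gap >= 0L & gap <= search_horizon_days
    cand <- cand[keep]
    n_candidates <- n_candidates + length(cand)
    if (length(cand) == 0) next
    ord <- order(disp$fill_date[cand], disp$disp_id[cand])
    pick <- cand[ord[1]]
    assigned[pick] <- TRUE
    out_disp[i] <- disp$disp_id[pick]
    out_days[i] <- as.integer(disp$fill_date[pick] - rx$rx_date[i])
  }

  links <- tibble(
    rx_id = rx$rx_id, patient_id = rx$patient_id, rx_date = rx$rx_date,
    disp_id = out_disp, days_to_fill = out_days,
    filled_within_cutoff = FALSE
  )
  result <- structure(
    list(
      links = links,
      unmatched_dispensings = disp$disp_id[!assigned],
      cutoff_days = NA_integer_,
      search_horizon_days = as.integer(search_horizon_days),
      diagnostics = list(
        n_prescriptions = n_rx,
        n_dispensings = nrow(disp),
        n_matched = sum(!is.na(out_disp)),
        n_candidates_evaluated = n_candidates,
        n_unknown_rxcui = n_unknown_rxcui,
        n_name_rejections = n_name_rejections
      )
    ),
    class = "linkage_result"
  )
  apply_fill_cutoff(result, cutoff_days)
}

#' @export
print.linkage_result <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<linkage_result> %d prescriptions, %d matched (%.1f%%), cutoff %d days\n",
    d$n_prescriptions, d$n_matched, 100 * d$n_matched / max(d$n_prescriptions, 1),
    x$cutoff_days
  ))
  invisible(x)
}

#' Label links by a fill-day cutoff
#'
#' A prescription counts as filled when a matched dispensing occurred within
#' `cutoff_days` of the prescribing date (same-day fills are day 0 and count).
#' Matches beyond the cutoff keep their `disp_id` but are labelled not filled.
#'
#' @param result A `linkage_result` from [match_fills()].
#' @param cutoff_days Positive integer, at most the search horizon used in
#'   matching.
#' @return The `linkage_result` with `filled_within_cutoff` and `cutoff_days`
#'   updated.
#' @export
apply_fill_cutoff <- function(result, cutoff_days = 30L) {
  stopifnot(inherits(result, "linkage_result"))
  if (!is_pos_int(cutoff_days)) {
    stop_config("`cutoff_days` must be a positive integer", "cutoff_days")
  }
  if (cutoff_days > result$search_horizon_days) {
    stop_config("`cutoff_days` cannot exceed the matching search horizon",
                "cutoff_days")
  }
  result$links$filled_within_cutoff <-
    !is.na(result$links$days_to_fill) &
    result$links$days_to_fill <= cutoff_days
  result$cutoff_days <- as.integer(cutoff_days)
  result
}

#' Kaplan-Meier curve of time from prescribing to fill
#'
#' Fill events occur at `days_to_fill`; never-matched prescriptions are
#' right-censored at `observation_end_days`.
#'
#' @param result A `linkage_result`.
#' @param observation_end_days Censoring time for unfilled prescriptions; must
#'   be at least the largest observed `days_to_fill`.
#' @return A `km_curve` (see [km_estimator()]).
#' @export
time_to_fill_curve <- function(result, observation_end_days = 365L) {
  stopifnot(inherits(result, "linkage_result"))
  days <- result$links$days_to_fill
  if (any(!is.na(days) & days > observation_end_days)) {
    stop_domain("`observation_end_days` is below the largest observed days_to_fill")
  }
  times <- ifelse(is.na(days), observation_end_days, days)
  km_estimator(times, events = !is.na(days))
}

#' Empirical distribution of days to fill
#'
#' Diagnostic companion to the cutoff choice: cumulative share of matched
#' fills at each observed day, for inspecting the inflection in fill timing.
#'
#' @param result A `linkage_result`.
#' @return Tibble with `days_to_fill`, `n`, `cum_fraction_of_matched`.
#' @export
days_to_fill_ecdf <- function(result) {
  stopifnot(inherits(result, "linkage_result"))
  result$links |>
    filter(!is.na(.data$days_to_fill)) |>
    count(.data$days_to_fill, name = "n") |>
    arrange(.data$days_to_fill) |>
    mutate(cum_fraction_of_matched = cumsum(.data$n) / sum(.data$n))
}
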