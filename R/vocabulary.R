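#' Normalize an NDC to 11-digit 5-4-2 form
#'
#' National Drug Codes appear in dispensing feeds in 10-digit segmented forms
#' (4-4-2, 5-3-2, or 5-4-1, usually dash-separated). The standard normalization
#' left-pads each segment to the 5-4-2 layout, yielding an 11-digit code.
#' Unsegmented input is stripped of separators and, when shorter than 11
#' digits, left-padded with zeros.
#'
#' @param ndc Character vector of NDC codes, with or without separators.
#' @return Character vector of 11-digit codes; `NA` where the input contains
#'   non-digit characters after separator removal (reported via warnings by
#'   [load_crosswalk()]).
#' @examples
#' normalize_ndc("1234-5678-90")  # 4-4-2 -> "01234567890"
#' normalize_ndc("12345-678-90")  # 5-3-2 -> "12345067890"
#' normalize_ndc("12345-6789-1")  # 5-4-1 -> "12345678901"
#' @export
normalize_ndc <- function(ndc) {
  vapply(ndc, normalize_ndc_one, character(1), USE.NAMES = FALSE)
}

normalize_ndc_one <- function(x) {
  if (is.na(x)) return(NA_character_)
  x <- trimws(x)
  segs <- strsplit(x, "[-. ]")[[1]]
  segs <- segs[nzchar(segs)]
  if (any(!grepl("^[0-9]+$", segs)) || length(segs) == 0) return(NA_character_)
  zero_pad <- function(s, width) {
    paste0(strrep("0", max(0L, width - nchar(s))), s)
  }
  if (length(segs) == 3) {
    widths <- c(5L, 4L, 2L)
    if (any(nchar(segs) > widths)) return(NA_character_)
    return(paste0(zero_pad(segs[1], 5L), zero_pad(segs[2], 4L),
                  zero_pad(segs[3], 2L)))
  }
  digits <- paste(segs, collapse = "")
  if (nchar(digits) > 11) return(NA_character_)
  zero_pad(digits, 11L)
}

#' Normalize a drug name for cross-ontology comparison
#'
#' Lowercases, strips punctuation, and collapses whitespace. Idempotent.
#'
#' @param x Character vector of drug names.
#' @return Normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9 ]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Leading alphabetic token of a normalized name: the ingredient.
ingredient_token <- function(x) {
  norm <- normalize_drug_name(x)
  token <- vapply(strsplit(norm, " "), function(tokens) {
    alpha <- tokens[grepl("^[a-z]", tokens)]
    if (length(alpha) == 0) "" else alpha[[1]]
  }, character(1))
  token
}

#' Load an RxCUI to NDC crosswalk
#'
#' Reads a delimited crosswalk with columns `rxcui`, `ndc`, `drug_name`
#' (an optional `drug_class` column, used for SSRI classification, is carried
#' through when present). Duplicate (rxcui, ndc) pairs are collapsed and NDCs
#' are normalized to 11-digit 5-4-2 form. Rows whose NDC cannot be normalized
#' are dropped and reported with a warning.
#'
#' @param path Path to a CSV crosswalk file.
#' @return A `medication_vocabulary` object: a list with `entries` (tibble of
#'   crosswalk rows with `normalized_name`) and `index` (named list mapping
#'   rxcui to its character vector of NDCs).
#' @export
load_crosswalk <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("crosswalk file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  check_columns(raw, c("rxcui", "ndc", "drug_name"), "crosswalk")
  raw$ndc_norm <- normalize_ndc(raw$ndc)
  bad <- which(is.na(raw$ndc_norm))
  if (length(bad) > 0) {
    warn(sprintf(
      "crosswalk: dropped %d row(s) with malformed NDC (rows %s)",
      length(bad), paste(head(bad, 10), collapse = ", ")
    ), class = "rxfill_ndc_warning")
    raw <- raw[-bad, , drop = FALSE]
  }
  entries <- raw |>
    mutate(ndc = .data$ndc_norm,
           normalized_name = normalize_drug_name(.data$drug_name)) |>
    select(-"ndc_norm") |>
    distinct(.data$rxcui, .data$ndc, .keep_all = TRUE)
  new_vocabulary(entries)
}

new_vocabulary <- function(entries) {
  entries <- as_tibble(entries)
  index <- split(entries$ndc, entries$rxcui)
  structure(list(entries = entries, index = index),
            class = "medication_vocabulary")
}

#' @export
print.medication_vocabulary <- function(x, ...) {
  cat(sprintf("<medication_vocabulary> %d entries, %d RxCUIs\n",
              nrow(x$entries), length(x$index)))
  invisible(x)
}

#' NDCs compatible with an RxCUI, validated by drug name
#'
#' Returns the NDCs mapped to `rxcui` whose crosswalk drug name shares the
#' leading ingredient token with `drug_name`. An empty `drug_name` bypasses
#' name validation and returns all NDCs for the RxCUI. Unknown RxCUIs return
#' an empty set (they are counted in linkage diagnostics, not errors).
#'
#' @param vocab A `medication_vocabulary`.
#' @param rxcui RxCUI identifier (length-1 character).
#' @param drug_name Free-text drug name from the prescribing record; may be
#'   `""` or `NA` to skip validation.
#' @return Character vector of 11-digit NDCs (possibly empty).
#' @export
ndcs_for_rxcui <- function(vocab, rxcui, drug_name = "") {
  stopifnot(inherits(vocab, "medication_vocabulary"))
  ndcs <- vocab$index[[as.character(rxcui)]]
  if (is.null(ndcs)) return(character(0))
  if (is.null(drug_name) || is.na(drug_name) || !nzchar(trimws(drug_name))) {
    return(ndcs)
  }
  query_token <- ingredient_token(drug_name)
  if (!nzchar(query_token)) return(ndcs)
  rows <- vocab$entries[vocab$entries$rxcui == as.character(rxcui), ]
  keep <- ingredient_token(rows$drug_name) == query_token
  rows$ndc[keep]
}

# Map rxcui -> drug_class (NA when absent); used for the SSRI covariate.
vocab_classes <- function(vocab) {
  entries <- vocab$entries
  if (!"drug_class" %in% names(entries)) {
    return(setNames(rep(NA_character_, length(vocab$index)), names(vocab$index)))
  }
  cls <- entries |>
    distinct(.data$rxcui, .data$drug_class)
  setNames(cls$drug_class, cls$rxcui)
}

# All NDCs known to the vocabulary (used for psychotropic dispensing checks).
vocab_ndcs <- function(vocab) unique(vocab$entries$ndc)

#' Path to the synthetic psychotropic crosswalk shipped with the package
#'
#' A small stand-in crosswalk (~20 psychotropic ingredients, synthetic RxCUI
#' and NDC identifiers) used by the data generator and examples.
#'
#' @return File path.
#' @export
default_crosswalk_path <- function() {
  system.file("extdata", "crosswalk_synthetic.csv", package = "rxfill",
              mustWork = TRUE)
}
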