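# Internal helpers shared across modules.

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(msg, field = NULL) {
  abort(msg, class = "rxfill_config_error", field = field)
}

stop_schema <- function(msg) abort(msg, class = "rxfill_schema_error")

stop_validation <- function(msg) abort(msg, class = "rxfill_validation_error")

stop_domain <- function(msg) abort(msg, class = "rxfill_domain_error")

stop_analysis <- function(msg) abort(msg, class = "rxfill_analysis_error")

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_schema(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Integer calendar year of a Date vector.
year_of <- function(x) as.integer(format(x, "%Y"))

# Completed years of age at a reference date.
age_at <- function(birth_date, ref_date) {
  as.integer(floor(as.numeric(ref_date - birth_date) / 365.25))
}

is_prop <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

is_pos_int <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x > 0 && x == floor(x)
}
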