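# Independent oracles used across the suite: simple exhaustive/stepping
# implementations that deliberately share no code with the package rules.

# random minute-precision date-times within 1995-2005
random_dts <- function(n) {
  make_dt(
    sample(1995:2005, n, replace = TRUE),
    sample(1:12, n, replace = TRUE),
    sample(1:28, n, replace = TRUE),
    sample(0:23, n, replace = TRUE),
    sample(0:59, n, replace = TRUE)
  )
}

# one-day-at-a-time backward stepping
oracle_step_days <- function(dt, k) {
  for (i in seq_len(k)) dt <- dt - 86400
  dt
}

# minute-count arithmetic for hour offsets
oracle_step_hours <- function(dt, k) {
  as.POSIXct(as.numeric(dt) - k * 60 * 60, origin = "1970-01-01", tz = "UTC")
}

make_result <- function(note_id, formatted, n_outputs = length(formatted)) {
  outs <- if (length(formatted) == 0) {
    tibble::tibble(
      onset = as.POSIXct(character(), tz = "UTC"),
      formatted = character()
    )
  } else {
    tibble::tibble(
      onset = parse_datetime(formatted, strict = FALSE),
      formatted = formatted
    )
  }
  list(note_id = note_id, outputs = outs, n_outputs = n_outputs)
}
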