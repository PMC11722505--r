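# Shared data model. Notes are rows of a tibble; time expressions are rows of
# a wide tibble whose optional fields are NA when absent. Character spans are
# 0-based, half-open, so raw == substr(text, start + 1, end) always.

NOTE_TYPES <- c("HP", "TRIAGE", "ED_SCREEN")

TE_KINDS <- c(
  "clock_hhmm", "clock_ampm", "military", "daypart", "wake_phrase",
  "relative_offset", "range", "partial_date", "year", "relative_word"
)

FORMAT_CATEGORIES <- c(
  "HHMM_COLON", "HH_AMPM", "MILITARY", "HOUR_PLUS_RELATIVE", "YYYY", "OTHER"
)

#' Construct a clinical note record
#'
#' @param note_id Opaque identifier.
#' @param note_type One of `"HP"` (History & Physical), `"TRIAGE"`,
#'   `"ED_SCREEN"` (ED screening / first contact).
#' @param note_datetime POSIXct note timestamp (minute precision), or a
#'   canonical `MM/DD/YYYY HH:MM` string.
#' @param text Free note text.
#' @return A one-row tibble with class `onsetdt_note`.
#' @examples
#' clinical_note("n1", "TRIAGE", "01/01/2000 08:35", "cp since 1 day ago")
#' @export
clinical_note <- function(note_id, note_type, note_datetime, text) {
  if (is.character(note_datetime)) {
    note_datetime <- parse_datetime(note_datetime, strict = FALSE)
  }
  note_type <- toupper(as.character(note_type))
  if (!note_type %in% NOTE_TYPES) {
    abort_onsetdt(
      sprintf(
        "note_type '%s' is not one of %s", note_type,
        paste(NOTE_TYPES, collapse = ", ")
      ),
      "onsetdt_schema_error"
    )
  }
  out <- tibble(
    note_id = as.character(note_id),
    note_type = note_type,
    note_datetime = trunc_minute(note_datetime),
    text = as.character(text)
  )
  class(out) <- c("onsetdt_note", class(out))
  out
}

# empty TimeExpression table, shared column order
te_empty <- function() {
  tibble(
    start = integer(), end = integer(), raw = character(),
    kind = character(), hour = integer(), minute = integer(),
    meridiem = character(), offset_quantity = double(),
    offset_unit = character(), rel_word = character(),
    range_a = character(), range_b = character(),
    month = integer(), day = integer(), year = integer(),
    format_category = character()
  )
}

te_row <- function(start, end, raw, kind,
                   hour = NA_integer_, minute = NA_integer_,
                   meridiem = NA_character_,
                   offset_quantity = NA_real_, offset_unit = NA_character_,
                   rel_word = NA_character_,
                   range_a = NA_character_, range_b = NA_character_,
                   month = NA_integer_, day = NA_integer_,
                   year = NA_integer_,
                   format_category = NA_character_) {
  tibble(
    start = as.integer(start), end = as.integer(end), raw = raw, kind = kind,
    hour = as.integer(hour), minute = as.integer(minute), meridiem = meridiem,
    offset_quantity = as.numeric(offset_quantity), offset_unit = offset_unit,
    rel_word = rel_word, range_a = range_a, range_b = range_b,
    month = as.integer(month), day = as.integer(day), year = as.integer(year),
    format_category = format_category
  )
}

validate_expressions <- function(exprs, text) {
  stopifnot(
    all(exprs$start >= 0), all(exprs$start < exprs$end),
    all(exprs$end <= nchar(text)),
    all(exprs$kind %in% TE_KINDS),
    all(substr(rep(text, nrow(exprs)), exprs$start + 1, exprs$end) == exprs$raw)
  )
  invisible(exprs)
}

# empty NormalizedOnset table
no_empty <- function() {
  tibble(
    start = integer(), end = integer(), raw = character(),
    stage = character(), onset = as.POSIXct(character(), tz = DT_TZ),
    formatted = character(), flagged = logical()
  )
}
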