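# Anchoring: conversion of a detected time expression into an absolute
# date-time relative to the note's timestamp. The governing assumption is
# that symptom onset precedes hospital presentation, so a clock time is
# placed on the note's day when that keeps it at or before the note
# date-time, and on the previous day otherwise.

#' Infer a missing meridiem for an ambiguous clock hour
#'
#' Hours 1-12 without an am/pm marker are disambiguated in two steps: if a
#' daypart cue (morning/afternoon/evening/night/meal words or a wake verb)
#' occurs in the surrounding sentence, its half of the day wins; otherwise
#' the candidate (am or pm) whose anchored date-time is latest while
#' remaining at or before the note date-time is chosen. Hours 0 and 13-23
#' are already unambiguous 24-hour values and bypass inference.
#'
#' @param hour Clock hour 0-23 (1-12 triggers inference).
#' @param minute Minutes (default 0).
#' @param context Surrounding sentence text (default empty).
#' @param note_dt POSIXct note date-time.
#' @return Integer hour 0-23.
#' @examples
#' infer_meridiem(4, 45, "chest pain since morning", make_dt(2000, 1, 3, 10, 0))
#' @export
infer_meridiem <- function(hour, minute = 0, context = "", note_dt) {
  hour <- as.integer(hour)
  if (hour == 0 || hour >= 13) {
    return(hour)
  }
  low <- tolower(context)
  am_cue <- str_detect(low, "\\b(morning|midmorning|dawn|overnight)\\b") ||
    str_detect(low, RX_WAKE_VERB)
  pm_cue <- str_detect(
    low, "\\b(afternoon|evening|tonight|night|noon|lunch|dinner|supper)\\b"
  )
  h_am <- hour %% 12L
  h_pm <- hour %% 12L + 12L
  if (am_cue && !pm_cue) {
    return(h_am)
  }
  if (pm_cue && !am_cue) {
    return(h_pm)
  }
  anchored <- c(
    anchor_clock(h_am, minute, note_dt),
    anchor_clock(h_pm, minute, note_dt)
  )
  c(h_am, h_pm)[which.max(as.numeric(anchored))]
}

to_hour24 <- function(hour, meridiem) {
  if (meridiem == "am") hour %% 12L else hour %% 12L + 12L
}

# relative-word alone -> anchored date-time (NULL if the word needs a clock)
REL_ALONE <- function(rel, note_dt) {
  day0 <- lubridate::floor_date(note_dt, "day")
  switch(rel,
    "today" = list(onset = note_dt, flagged = FALSE),
    "yesterday" = list(onset = note_dt - 86400, flagged = FALSE),
    "last night" = list(onset = day0 - 86400 + 22 * 3600, flagged = FALSE),
    "last evening" = list(onset = day0 - 86400 + 22 * 3600, flagged = FALSE),
    "tonight" = list(onset = anchor_clock(22, 0, note_dt), flagged = FALSE),
    "this evening" = list(onset = anchor_clock(22, 0, note_dt), flagged = FALSE),
    "this morning" = list(onset = anchor_clock(7, 0, note_dt), flagged = FALSE),
    "this afternoon" = list(onset = anchor_clock(15, 0, note_dt), flagged = FALSE),
    "last week" = list(onset = note_dt - 7 * 86400, flagged = FALSE),
    "next week" = list(onset = note_dt + 7 * 86400, flagged = TRUE),
    NULL
  )
}

# compound (clock + relative word) day placement:
#  - yesterday / last evening: previous calendar day, always
#  - last night with a pm time: previous day; with an am time the early
#    hours belong to the note's own day when that keeps onset <= note_dt
#  - today / tonight / this *: note's day; flagged and shifted back one day
#    if that would land after the note
anchor_compound <- function(hour24, minute, rel, note_dt) {
  day0 <- lubridate::floor_date(note_dt, "day")
  secs <- hour24 * 3600 + minute * 60
  if (rel %in% c("yesterday", "last evening")) {
    return(list(onset = day0 - 86400 + secs, flagged = FALSE))
  }
  if (rel == "last night" && hour24 >= 12) {
    return(list(onset = day0 - 86400 + secs, flagged = FALSE))
  }
  cand <- day0 + secs
  if (rel %in% c("last night")) {
    return(list(onset = if (cand > note_dt) cand - 86400 else cand, flagged = FALSE))
  }
  if (cand > note_dt) {
    return(list(onset = cand - 86400, flagged = TRUE))
  }
  list(onset = cand, flagged = FALSE)
}

# one expression row -> list(onset = POSIXct, flagged = logical)
anchor_expression <- function(expr, note_dt, context = "") {
  kind <- expr$kind
  if (kind == "range") {
    chosen <- resolve_range(expr$range_a, expr$range_b, note_dt)
    return(list(onset = attr(chosen, "onset"), flagged = FALSE))
  }
  if (kind == "relative_offset") {
    onset <- resolve_relative_offset(
      expr$offset_quantity, expr$offset_unit, note_dt
    )
    return(list(onset = onset, flagged = FALSE))
  }
  if (kind == "partial_date") {
    y <- expr$year
    explicit_year <- !is.na(y)
    if (!explicit_year) y <- lubridate::year(note_dt)
    onset <- make_dt(y, expr$month, expr$day, 0, 0)
    if (!explicit_year && onset > note_dt) {
      onset <- make_dt(y - 1L, expr$month, expr$day, 0, 0)
    }
    return(list(onset = onset, flagged = onset > note_dt))
  }
  if (kind == "year") {
    onset <- make_dt(expr$year, 1, 1, 0, 0)
    return(list(onset = onset, flagged = onset > note_dt))
  }
  if (kind %in% c("daypart", "wake_phrase")) {
    hm <- lookup_daypart(expr$raw)
    if (is.null(hm)) {
      abort_onsetdt(
        sprintf("no lexicon rule for phrase '%s'", expr$raw),
        "onsetdt_flagged_error"
      )
    }
    return(list(onset = anchor_clock(hm$hour, hm$minute, note_dt), flagged = FALSE))
  }
  if (kind == "relative_word" && is.na(expr$hour)) {
    res <- REL_ALONE(tolower(str_squish(expr$rel_word)), note_dt)
    if (is.null(res)) {
      abort_onsetdt(
        sprintf("cannot anchor relative word '%s'", expr$rel_word),
        "onsetdt_flagged_error"
      )
    }
    return(res)
  }
  # clock-bearing kinds (clock_ampm, clock_hhmm, military), possibly
  # combined with a relative word
  hour <- expr$hour
  minute <- if (is.na(expr$minute)) 0L else expr$minute
  hour24 <- if (!is.na(expr$meridiem)) {
    to_hour24(hour, expr$meridiem)
  } else if (kind == "military" || hour == 0 || hour >= 13) {
    hour
  } else {
    infer_meridiem(hour, minute, context, note_dt)
  }
  rel <- expr$rel_word
  if (!is.na(rel)) {
    return(anchor_compound(hour24, minute, tolower(str_squish(rel)), note_dt))
  }
  list(onset = anchor_clock(hour24, minute, note_dt), flagged = FALSE)
}

# anchor a table of expressions; returns a NormalizedOnset table in the same
# order, with stage "lexicon" for rule-lookup anchors
anchor_table <- function(exprs, note_dt, text, stage) {
  if (nrow(exprs) == 0) {
    return(no_empty())
  }
  rows <- lapply(seq_len(nrow(exprs)), function(i) {
    e <- exprs[i, ]
    res <- anchor_expression(e, note_dt, sentence_of(text, e$start))
    tibble(
      start = e$start, end = e$end, raw = e$raw,
      stage = if (e$kind %in% c("daypart", "wake_phrase")) "lexicon" else stage,
      onset = trunc_minute(res$onset),
      formatted = format_datetime(res$onset),
      flagged = res$flagged
    )
  })
  list_rbind(rows)
}
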