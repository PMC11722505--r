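# Rules for unspecified or relative symptom onset times: backward offset
# arithmetic, time-range resolution, and the most-recent-episode rule. Onset
# always precedes hospital presentation, so resolved values never anchor
# after the note's own timestamp.

#' Step a note's date-time backward by a relative offset
#'
#' Implements the days-ago rule ("same hour time with 24-hour increment
#' backward") and its hour/week analogues: days and weeks preserve the clock
#' time (a week is seven days); hours are exact 60-minute steps; months (an
#' extension, not part of the published rule set) use calendar-month
#' arithmetic with day-of-month clamping.
#'
#' @param quantity Non-negative count.
#' @param unit One of `"hour"`, `"day"`, `"week"`, `"month"`.
#' @param note_dt POSIXct note date-time (the anchor).
#' @return POSIXct onset date-time.
#' @examples
#' resolve_relative_offset(1, "day", make_dt(2000, 1, 1, 8, 35))
#' @export
resolve_relative_offset <- function(quantity, unit, note_dt) {
  stopifnot(quantity >= 0, inherits(note_dt, "POSIXct"))
  unit <- match.arg(unit, c("hour", "day", "week", "month"))
  out <- switch(unit,
    hour = note_dt - quantity * 3600,
    day = note_dt - quantity * 86400,
    week = note_dt - quantity * 7 * 86400,
    month = note_dt %m-% months(as.integer(quantity))
  )
  if (lubridate::year(out) < 1900) {
    abort_onsetdt(
      sprintf("offset of %g %ss lands before 1900", quantity, unit),
      "onsetdt_range_error"
    )
  }
  trunc_minute(out)
}

# place a clock time on the note's day if that keeps onset <= note_dt,
# otherwise on the previous day
anchor_clock <- function(hour, minute, note_dt) {
  cand <- lubridate::floor_date(note_dt, "day") + hour * 3600 + minute * 60
  if (cand > note_dt) cand <- cand - 86400
  cand
}

#' Resolve a time range to a single endpoint
#'
#' When a note gives a range ("0200-0300", "2-3 days ago"), the symptom is
#' assumed intermittent and the endpoint whose anchored date-time is closest
#' to — and not after — the note's date-time is kept (mimicking the
#' most-recent-episode rule). For clock-time ranges this is the later clock
#' time; for "ago" ranges, the smaller offset.
#'
#' @param endpoint_a,endpoint_b Endpoint expressions: single-token strings
#'   (e.g. `"0300"`, `"2 days ago"`) or one-row expression tibbles from
#'   [time_expr()].
#' @param note_dt POSIXct note date-time.
#' @return The chosen endpoint as a one-row expression tibble, with the
#'   anchored POSIXct date-time in attribute `"onset"`.
#' @examples
#' resolve_range("0200", "0300", make_dt(2000, 1, 1, 9, 0))$raw
#' @export
resolve_range <- function(endpoint_a, endpoint_b, note_dt) {
  eps <- list(endpoint_a, endpoint_b)
  eps <- lapply(eps, function(e) if (is.character(e)) time_expr(e) else e)
  anchored <- lapply(eps, function(e) anchor_expression(e, note_dt, e$raw))
  onsets <- do.call(c, lapply(anchored, `[[`, "onset"))
  ok <- which(onsets <= note_dt)
  if (length(ok) == 0) {
    abort_onsetdt(
      "neither range endpoint anchors at or before the note date-time",
      "onsetdt_flagged_error"
    )
  }
  pick <- ok[which.max(as.numeric(onsets[ok]))]
  out <- eps[[pick]]
  attr(out, "onset") <- onsets[pick]
  out
}

#' Select the most recent onset candidate before presentation
#'
#' The intermittent-symptom rule: when several onset candidates exist, keep
#' the most recent one that does not fall after the note's date-time.
#'
#' @param candidates POSIXct vector of candidate onsets (non-empty).
#' @param note_dt POSIXct note date-time.
#' @return POSIXct scalar.
#' @examples
#' select_most_recent(
#'   c(make_dt(1999, 12, 30, 21, 0), make_dt(1999, 12, 31, 3, 0)),
#'   make_dt(1999, 12, 31, 8, 0)
#' )
#' @export
select_most_recent <- function(candidates, note_dt) {
  stopifnot(length(candidates) > 0, inherits(candidates, "POSIXct"))
  ok <- candidates[candidates <= note_dt]
  if (length(ok) == 0) {
    abort_onsetdt(
      "all onset candidates fall after the note date-time",
      "onsetdt_flagged_error"
    )
  }
  max(ok)
}
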