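# Canonical date-time handling. All date-times are timezone-naive at minute
# precision; internally they are POSIXct in UTC (no DST, so day arithmetic in
# seconds is exact) with seconds truncated.

DT_TZ <- "UTC"
DT_FORMAT <- "%m/%d/%Y %H:%M"

#' Build a minute-precision date-time
#'
#' Convenience constructor for the package's internal date-time representation
#' (POSIXct, UTC, seconds zero).
#'
#' @param year,month,day,hour,minute Integer components.
#' @return A POSIXct scalar (or vector, components recycle).
#' @examples
#' make_dt(2000, 1, 1, 8, 35)
#' @export
make_dt <- function(year, month, day, hour = 0, minute = 0) {
  dt <- ISOdatetime(year, month, day, hour, minute, 0, tz = DT_TZ)
  if (any(is.na(dt))) {
    abort_onsetdt("invalid calendar date-time components", "onsetdt_parse_error")
  }
  dt
}

# drop seconds (and any sub-second part)
trunc_minute <- function(dt) {
  as.POSIXct(floor(as.numeric(dt) / 60) * 60,
    origin = "1970-01-01", tz = DT_TZ
  )
}

#' Render a date-time in the canonical `MM/DD/YYYY HH:MM` format
#'
#' The canonical output format used across both pipelines and by the
#' evaluation harness. Zero-padded, month first, minute precision (seconds
#' are truncated).
#'
#' @param dt POSIXct date-time(s).
#' @return Character vector, e.g. `"12/31/1999 08:35"`.
#' @seealso [parse_datetime()] for the exact inverse.
#' @examples
#' format_datetime(make_dt(1999, 12, 31, 8, 35))
#' @export
format_datetime <- function(dt) {
  stopifnot(inherits(dt, "POSIXct"))
  format(trunc_minute(dt), DT_FORMAT, tz = DT_TZ)
}

#' Parse the canonical `MM/DD/YYYY HH:MM` format
#'
#' Exact inverse of [format_datetime()]. Strict by default: fields must be
#' zero-padded (evaluation uses exact string match, so canonical strings are
#' unambiguous); `strict = FALSE` accepts unpadded month/day/hour.
#'
#' @param s Character vector of canonical date-time strings.
#' @param strict Require zero-padded fields (default `TRUE`).
#' @return POSIXct vector.
#' @examples
#' parse_datetime("12/31/1999 08:35")
#' @export
parse_datetime <- function(s, strict = TRUE) {
  pat <- if (strict) {
    "^([0-9]{2})/([0-9]{2})/([0-9]{4}) ([0-9]{2}):([0-9]{2})$"
  } else {
    "^([0-9]{1,2})/([0-9]{1,2})/([0-9]{4}) ([0-9]{1,2}):([0-9]{2})$"
  }
  m <- str_match(s, pat)
  if (any(is.na(m[, 1]))) {
    bad <- s[is.na(m[, 1])][1]
    abort_onsetdt(
      sprintf(
        "'%s' does not match the canonical %sMM/DD/YYYY HH:MM format",
        bad, if (strict) "zero-padded " else ""
      ),
      "onsetdt_parse_error"
    )
  }
  mo <- as.integer(m[, 2])
  d <- as.integer(m[, 3])
  y <- as.integer(m[, 4])
  h <- as.integer(m[, 5])
  mi <- as.integer(m[, 6])
  check_field <- function(bad, field) {
    if (any(bad)) {
      abort_onsetdt(
        sprintf("invalid %s in date-time string '%s'", field, s[bad][1]),
        "onsetdt_parse_error"
      )
    }
  }
  check_field(mo < 1 | mo > 12, "month")
  check_field(h > 23, "hour")
  check_field(mi > 59, "minute")
  dim_ok <- as.integer(lubridate::days_in_month(as.Date(
    sprintf("%04d-%02d-01", y, mo)
  )))
  check_field(d < 1 | d > dim_ok, "day")
  make_dt(y, mo, d, h, mi)
}
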