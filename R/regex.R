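# The regex pipeline: six case-insensitive pattern families applied with a
# fixed precedence (longest match first, then family order 4 > 1 > 2 > 3 >
# 5 > 6) so that e.g. "0530 today" is kept as one combined expression rather
# than splitting into a military time plus a relative word.
#
# Families: (1) HH:MM 24-hour clock, (2) hour with am/pm, (3) 4-digit
# military time, (4) hour time + relative word combinations, (5) month-name
# and numeric dates, (6) standalone relative words and 4-digit years.

#' Extract temporal expressions with the six-family regex suite
#'
#' Applies the six pattern families case-insensitively and returns
#' non-overlapping matches in document order, each labeled with a format
#' category (`HHMM_COLON`, `HH_AMPM`, `MILITARY`, `HOUR_PLUS_RELATIVE`,
#' `YYYY`, `OTHER`). Ambiguous 4-digit tokens in 1900-2099 ("2004") are
#' read as years unless a time cue precedes them or a relative word follows.
#'
#' @param text Note text.
#' @return A time-expression tibble with `format_category` set.
#' @examples
#' extract_expressions_regex("ekg done at 20:30")$format_category
#' extract_expressions_regex("CABG in 2004")$format_category
#' @export
extract_expressions_regex <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(te_empty())
  }
  cands <- list()
  add <- function(df, family) {
    if (nrow(df) > 0) {
      df$family <- family
      cands[[length(cands) + 1]] <<- df
    }
  }

  # family 4: time + relative word (either order)
  cf <- scan_pattern(text, paste0(
    "(", P_TIME_TOK, ")\\s+(?:of\\s+)?(", P_RELWORD, ")"
  ))
  if (nrow(cf) > 0) {
    cf <- bind_cols(
      cf[c("start", "end", "raw")],
      list_rbind(map(cf$g1, function(tok) {
        f <- parse_clock_token(tok)
        tibble(
          kind = clock_token_kind(tok), hour = f$hour, minute = f$minute,
          meridiem = f$meridiem
        )
      })),
      tibble(
        rel_word = str_squish(tolower(cf$g2)),
        format_category = "HOUR_PLUS_RELATIVE"
      )
    )
    add(cf, 4)
  }
  rf <- scan_pattern(text, paste0(
    "\\b(", P_RELWORD, ")\\s+(?:(?:at|around|about|approx\\.?|~)\\s+)?(",
    P_TIME_TOK, ")"
  ))
  if (nrow(rf) > 0) {
    rf <- bind_cols(
      rf[c("start", "end", "raw")],
      list_rbind(map(rf$g2, function(tok) {
        f <- parse_clock_token(tok)
        tibble(
          kind = clock_token_kind(tok), hour = f$hour, minute = f$minute,
          meridiem = f$meridiem
        )
      })),
      tibble(
        rel_word = str_squish(tolower(rf$g1)),
        format_category = "HOUR_PLUS_RELATIVE"
      )
    )
    add(rf, 4)
  }

  # family 1: HH:MM without meridiem
  hc <- scan_pattern(text, P_HHMM_NOAMPM)
  if (nrow(hc) > 0) {
    fields <- map(hc$raw, parse_clock_token)
    hc <- tibble(
      start = hc$start, end = hc$end, raw = hc$raw, kind = "clock_hhmm",
      hour = map_int(fields, "hour"), minute = map_int(fields, "minute"),
      format_category = "HHMM_COLON"
    )
    add(hc, 1)
  }

  # family 2: hour with am/pm
  ca <- scan_pattern(text, P_CLOCK_AMPM)
  if (nrow(ca) > 0) {
    fields <- map(ca$raw, parse_clock_token)
    ca <- tibble(
      start = ca$start, end = ca$end, raw = ca$raw, kind = "clock_ampm",
      hour = map_int(fields, "hour"), minute = map_int(fields, "minute"),
      meridiem = map_chr(fields, "meridiem"),
      format_category = "HH_AMPM"
    )
    add(ca, 2)
  }

  # family 3: 4-digit military, years excluded unless a time cue precedes
  mil <- scan_pattern(text, P_MIL)
  if (nrow(mil) > 0) {
    val <- as.integer(mil$raw)
    ambiguous <- val >= 1900 & val <= 2099
    cued <- vapply(mil$start, function(s) {
      str_detect(substr(text, 1, s), regex(P_TIME_CUE_BEFORE,
        ignore_case = TRUE
      ))
    }, logical(1))
    mil <- mil[!ambiguous | cued, ]
    if (nrow(mil) > 0) {
      fields <- map(mil$raw, parse_clock_token)
      mil <- tibble(
        start = mil$start, end = mil$end, raw = mil$raw, kind = "military",
        hour = map_int(fields, "hour"), minute = map_int(fields, "minute"),
        format_category = "MILITARY"
      )
      add(mil, 3)
    }
  }

  # family 5: month-name and numeric dates
  md <- scan_pattern(text, P_MONTHDATE)
  if (nrow(md) > 0) {
    md <- tibble(
      start = md$start, end = md$end, raw = md$raw, kind = "partial_date",
      month = unname(MONTH_ABBR[tolower(substr(md$g1, 1, 3))]),
      day = as.integer(md$g2), year = as.integer(md$g3),
      format_category = "OTHER"
    )
    add(md, 5)
  }
  nd <- scan_pattern(text, P_NUMDATE)
  if (nrow(nd) > 0) {
    yr <- as.integer(nd$g3)
    yr <- ifelse(!is.na(yr) & yr < 100, yr + 2000L, yr)
    nd <- tibble(
      start = nd$start, end = nd$end, raw = nd$raw, kind = "partial_date",
      month = as.integer(nd$g1), day = as.integer(nd$g2), year = yr,
      format_category = "OTHER"
    )
    add(nd, 5)
  }

  # family 6: standalone relative words and 4-digit years
  rw <- scan_pattern(text, paste0("\\b(", P_RELWORD, "|", P_DAYPART, ")\\b"))
  if (nrow(rw) > 0) {
    rw <- tibble(
      start = rw$start, end = rw$end, raw = rw$raw,
      kind = ifelse(
        str_detect(tolower(rw$raw), regex(paste0("^", P_RELWORD, "$"))),
        "relative_word", "daypart"
      ),
      rel_word = str_squish(tolower(rw$raw)),
      format_category = "OTHER"
    )
    rw$rel_word[rw$kind == "daypart"] <- NA_character_
    add(rw, 6)
  }
  yr <- scan_pattern(text, P_YEAR)
  if (nrow(yr) > 0) {
    yr <- tibble(
      start = yr$start, end = yr$end, raw = yr$raw, kind = "year",
      year = as.integer(yr$raw), format_category = "YYYY"
    )
    add(yr, 6)
  }

  if (length(cands) == 0) {
    return(te_empty())
  }
  all <- bind_rows(te_empty(), list_rbind(cands))
  # precedence: longest match first, family order breaking ties
  family_rank <- c(`4` = 1, `1` = 2, `2` = 3, `3` = 4, `5` = 5, `6` = 6)
  all$prio <- family_rank[as.character(all$family)] +
    (max(all$end - all$start) - (all$end - all$start)) * 10
  out <- resolve_overlaps(all)
  out$prio <- NULL
  out$family <- NULL
  validate_expressions(as_tibble(out), text)
}

#' Format category of a detected expression
#'
#' Deterministic Table-style category label for an expression produced by
#' either pipeline: exactly one of `HHMM_COLON`, `HH_AMPM`, `MILITARY`,
#' `HOUR_PLUS_RELATIVE`, `YYYY`, `OTHER`.
#'
#' @param expr One-row (or multi-row) time-expression tibble.
#' @return Character vector of category labels.
#' @examples
#' categorize_format(extract_expressions_regex("pain at 11:30 am"))
#' @export
categorize_format <- function(expr) {
  filled <- assign_format_category(expr)
  out <- ifelse(is.na(expr$format_category),
    filled$format_category, expr$format_category
  )
  stopifnot(all(out %in% FORMAT_CATEGORIES))
  out
}

#' Anchor regex-suite expressions to a note date-time
#'
#' In `"faithful"` mode this returns an empty table for any input: the
#' published regex pipeline produced no outputs in the canonical
#' `MM/DD/YYYY HH:MM` format, only raw expression strings. `"extended"`
#' mode anchors each expression through the onset rule set exactly like the
#' hybrid pipeline does.
#'
#' @param exprs Time-expression tibble from [extract_expressions_regex()].
#' @param note_dt POSIXct note date-time.
#' @param mode `"faithful"` (default) or `"extended"`.
#' @param text Original note text (context for meridiem inference; defaults
#'   to the expressions' own raw strings).
#' @return A normalized-onset tibble (always empty in faithful mode).
#' @examples
#' exprs <- extract_expressions_regex("cp since 0530 today")
#' anchor_regex_outputs(exprs, make_dt(2000, 1, 5, 9, 0), mode = "extended")
#' @export
anchor_regex_outputs <- function(exprs, note_dt,
                                 mode = c("faithful", "extended"),
                                 text = NULL) {
  mode <- match.arg(mode)
  if (mode == "faithful" || nrow(exprs) == 0) {
    return(no_empty())
  }
  text <- text %||% paste(exprs$raw, collapse = " ")
  anchor_table(exprs, note_dt, text, "primary")
}
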