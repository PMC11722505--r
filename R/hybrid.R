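# The hybrid pipeline: a primary recognizer for human-readable date-time
# phrases (relative words, backward offsets, clock times with meridiem,
# compounds, partial dates, lexicon triggers) and a fallback scanner for
# explicit numeric times that fires when the primary pass finds nothing.

# assign the Table-3-style format category; total over detected expressions
assign_format_category <- function(exprs) {
  if (nrow(exprs) == 0) {
    return(exprs)
  }
  exprs$format_category <- vapply(seq_len(nrow(exprs)), function(i) {
    e <- exprs[i, ]
    if (!is.na(e$rel_word) && !is.na(e$hour)) {
      "HOUR_PLUS_RELATIVE"
    } else if (e$kind == "clock_ampm") {
      "HH_AMPM"
    } else if (e$kind == "clock_hhmm") {
      "HHMM_COLON"
    } else if (e$kind == "military") {
      "MILITARY"
    } else if (e$kind == "year") {
      "YYYY"
    } else {
      "OTHER"
    }
  }, character(1))
  exprs
}

unit_follows <- function(text, end) {
  str_detect(substr(text, end + 1, nchar(text)), regex(P_UNIT_AFTER,
    ignore_case = TRUE
  ))
}

# a daypart trigger immediately followed by a dotted-clock token (e.g.
# "morning 4.45 am") elaborates an explicit time the primary grammar does
# not cover; the trigger is suppressed so the note falls through to the
# fallback scanner
daypart_before_dotted_time <- function(text, end) {
  str_detect(substr(text, end + 1, nchar(text)),
    regex("^\\W{0,3}\\d{1,2}\\.[0-5][0-9]\\b", ignore_case = TRUE)
  )
}

clock_fields <- function(cand) {
  ct <- parse_clock_token(cand)
  list(hour = ct$hour, minute = ct$minute, meridiem = ct$meridiem)
}

#' Primary detection of date-time phrases in note text
#'
#' Detects, in document order: compound phrases ("last night at 9 pm",
#' "3AM today"), time ranges, backward offsets ("2 days ago", "four hours
#' ago"), clock times, partial and month-name dates, standalone relative
#' words, and daypart/wake triggers from the rule lexicon. With
#' `distractor_guard = TRUE` (used in extended mode) bare numerals followed
#' by dose/count tokens ("6 mg", "6 stents") are never treated as times;
#' without it the recognizer reproduces the known failure mode of naive
#' date-time parsing on clinical text.
#'
#' @param text Note text.
#' @param note_dt POSIXct note date-time (reference; detection itself does
#'   not depend on it, anchoring does).
#' @param distractor_guard Suppress bare numerals adjacent to unit tokens.
#' @return A time-expression tibble (possibly empty), 0-based half-open
#'   spans, one `format_category` per row.
#' @examples
#' note_dt <- make_dt(2000, 1, 2, 10, 15)
#' parse_primary("c/o cp which began last night at 9 pm", note_dt)
#' @export
parse_primary <- function(text, note_dt, distractor_guard = FALSE) {
  if (is.na(text) || !nzchar(text)) {
    return(assign_format_category(te_empty()))
  }
  cands <- list()
  add <- function(df, prio) {
    if (nrow(df) > 0) {
      df$prio <- prio
      cands[[length(cands) + 1]] <<- df
    }
  }

  cf <- scan_pattern(text, paste0(
    "(", P_TIME_TOK, ")\\s+(?:of\\s+)?(", P_RELWORD, ")"
  ))
  if (nrow(cf) > 0) {
    cf <- bind_cols(
      cf[c("start", "end", "raw")],
      list_rbind(map(cf$g1, function(tok) {
        f <- clock_fields(tok)
        tibble(
          kind = clock_token_kind(tok), hour = f$hour,
          minute = f$minute, meridiem = f$meridiem
        )
      })),
      tibble(rel_word = str_squish(tolower(cf$g2)))
    )
    add(cf, 1)
  }
  rf <- scan_pattern(text, paste0(
    "\\b(", P_RELWORD, ")\\s+(?:(?:at|around|about|approx\\.?|~)\\s+)?(",
    P_TIME_TOK, ")"
  ))
  if (nrow(rf) > 0) {
    rf <- bind_cols(
      rf[c("start", "end", "raw")],
      list_rbind(map(rf$g2, function(tok) {
        f <- clock_fields(tok)
        tibble(
          kind = clock_token_kind(tok), hour = f$hour,
          minute = f$minute, meridiem = f$meridiem
        )
      })),
      tibble(rel_word = str_squish(tolower(rf$g1)))
    )
    add(rf, 2)
  }

  ra <- scan_pattern(text, P_RANGE_AGO)
  if (nrow(ra) > 0) {
    unit <- tolower(ra$g3)
    ra <- tibble(
      start = ra$start, end = ra$end, raw = ra$raw, kind = "range",
      offset_unit = map_chr(unit, offset_unit_value),
      range_a = paste(ra$g1, unit, "ago"),
      range_b = paste(ra$g2, unit, "ago")
    )
    add(ra, 3)
  }
  rc <- scan_pattern(text, P_RANGE_CLOCK)
  if (nrow(rc) > 0) {
    suffix <- ifelse(is.na(rc$g3), "", rc$g3)
    rc <- tibble(
      start = rc$start, end = rc$end, raw = rc$raw, kind = "range",
      range_a = str_squish(paste0(rc$g1, suffix)),
      range_b = str_squish(paste0(rc$g2, suffix))
    )
    add(rc, 4)
  }
  rm <- scan_pattern(text, P_RANGE_AMPM)
  if (nrow(rm) > 0) {
    rm <- tibble(
      start = rm$start, end = rm$end, raw = rm$raw, kind = "range",
      range_a = paste(rm$g1, rm$g3), range_b = paste(rm$g2, rm$g3)
    )
    add(rm, 5)
  }

  off <- scan_pattern(text, P_OFFSET)
  if (nrow(off) > 0) {
    off <- tibble(
      start = off$start, end = off$end, raw = off$raw,
      kind = "relative_offset",
      offset_quantity = map_dbl(off$g1, offset_quantity_value),
      offset_unit = map_chr(off$g2, offset_unit_value)
    )
    add(off, 6)
  }

  ca <- scan_pattern(text, P_CLOCK_AMPM)
  if (nrow(ca) > 0) {
    ca <- bind_cols(
      ca[c("start", "end", "raw")],
      list_rbind(map(ca$raw, function(tok) {
        f <- clock_fields(tok)
        tibble(
          kind = "clock_ampm", hour = f$hour, minute = f$minute,
          meridiem = f$meridiem
        )
      }))
    )
    add(ca, 7)
  }
  hc <- scan_pattern(text, P_HHMM_NOAMPM)
  if (nrow(hc) > 0) {
    hc <- bind_cols(
      hc[c("start", "end", "raw")],
      list_rbind(map(hc$raw, function(tok) {
        f <- clock_fields(tok)
        tibble(kind = "clock_hhmm", hour = f$hour, minute = f$minute)
      }))
    )
    add(hc, 8)
  }

  nd <- scan_pattern(text, P_NUMDATE)
  if (nrow(nd) > 0) {
    yr <- as.integer(nd$g3)
    yr <- ifelse(!is.na(yr) & yr < 100, yr + 2000L, yr)
    nd <- tibble(
      start = nd$start, end = nd$end, raw = nd$raw, kind = "partial_date",
      month = as.integer(nd$g1), day = as.integer(nd$g2), year = yr
    )
    add(nd, 9)
  }
  md <- scan_pattern(text, P_MONTHDATE)
  if (nrow(md) > 0) {
    md <- tibble(
      start = md$start, end = md$end, raw = md$raw, kind = "partial_date",
      month = unname(MONTH_ABBR[tolower(substr(md$g1, 1, 3))]),
      day = as.integer(md$g2), year = as.integer(md$g3)
    )
    add(md, 10)
  }

  wk <- scan_pattern(text, P_WAKE)
  if (nrow(wk) > 0) {
    wk$kind <- "wake_phrase"
    add(wk[c("start", "end", "raw", "kind")], 11)
  }
  rw <- scan_pattern(text, paste0("\\b(", P_RELWORD, ")\\b"))
  if (nrow(rw) > 0) {
    rw <- tibble(
      start = rw$start, end = rw$end, raw = rw$raw,
      kind = "relative_word", rel_word = str_squish(tolower(rw$raw))
    )
    add(rw, 12)
  }
  dp <- scan_pattern(text, P_DAYPART)
  if (nrow(dp) > 0) {
    keep <- !vapply(dp$end, function(e) daypart_before_dotted_time(text, e),
      logical(1)
    )
    dp <- dp[keep, ]
    if (nrow(dp) > 0) {
      dp$kind <- "daypart"
      add(dp[c("start", "end", "raw", "kind")], 13)
    }
  }

  bn <- scan_pattern(text, P_BARE_NUM)
  if (nrow(bn) > 0) {
    if (distractor_guard) {
      bn <- bn[!vapply(bn$end, function(e) unit_follows(text, e), logical(1)), ]
    }
    if (nrow(bn) > 0) {
      bn <- tibble(
        start = bn$start, end = bn$end, raw = bn$raw,
        kind = "clock_ampm", hour = as.integer(bn$raw), minute = 0L
      )
      add(bn, 14)
    }
  }

  if (length(cands) == 0) {
    return(assign_format_category(te_empty()))
  }
  out <- resolve_overlaps(bind_rows(te_empty(), list_rbind(cands)))
  out$prio <- NULL
  out <- assign_format_category(as_tibble(out))
  validate_expressions(out, text)
}

#' Correct dotted time punctuation
#'
#' Rewrites the `.` separator of a clock-shaped token to `:` ("4.45 am" to
#' "4:45 am"). Only tokens that are plausibly times are touched: the minutes
#' field must be two digits 00-59, so dose-like values ("4.5 mg") pass
#' through unchanged.
#'
#' @param token Character vector of candidate tokens.
#' @return Character vector with time punctuation corrected.
#' @examples
#' correct_time_punctuation("4.45 am")
#' correct_time_punctuation("4.5 mg")
#' @export
correct_time_punctuation <- function(token) {
  is_time <- str_detect(token, regex(
    "^\\s*\\d{1,2}\\.[0-5][0-9]\\s*(?:a\\.?m\\.?|p\\.?m\\.?)?\\s*$",
    ignore_case = TRUE
  ))
  ifelse(is_time, str_replace(token, fixed("."), ":"), token)
}

#' Fallback scanner for explicit numeric times
#'
#' Used when primary parsing finds nothing: scans for explicit time mentions
#' (H:MM / H.MM with optional am/pm, 4-digit military times, cue-marked bare
#' hours such as "since 7"), corrects dotted punctuation, and leaves missing
#' meridiem to be inferred from sentence context at anchoring time.
#'
#' @inheritParams parse_primary
#' @return A time-expression tibble in document order.
#' @examples
#' parse_fallback(
#'   "complains of chest pain since morning 4.45 am",
#'   make_dt(2000, 1, 3, 11, 0)
#' )
#' @export
parse_fallback <- function(text, note_dt, distractor_guard = FALSE) {
  if (is.na(text) || !nzchar(text)) {
    return(assign_format_category(te_empty()))
  }
  cands <- list()
  add <- function(df, prio) {
    if (nrow(df) > 0) {
      df$prio <- prio
      cands[[length(cands) + 1]] <<- df
    }
  }

  f1 <- scan_pattern(text, paste0(
    "(?<![0-9.:])\\b\\d{1,2}[.:][0-5][0-9]\\s*(", P_AMPM, ")?(?![.:]?[0-9])"
  ))
  if (nrow(f1) > 0) {
    f1$raw <- str_trim(f1$raw)
    f1$end <- f1$start + nchar(f1$raw)
    fields <- map(correct_time_punctuation(f1$raw), parse_clock_token)
    f1 <- tibble(
      start = f1$start, end = f1$end, raw = f1$raw,
      kind = ifelse(is.na(f1$g1), "clock_hhmm", "clock_ampm"),
      hour = map_int(fields, "hour"), minute = map_int(fields, "minute"),
      meridiem = map_chr(fields, function(f) f$meridiem %||% NA_character_)
    )
    # dotted tokens without a meridiem next to a unit are doses, not times
    dotted <- str_detect(f1$raw, fixed("."))
    drop <- f1$hour > 23 |
      (dotted & is.na(f1$meridiem) &
        vapply(f1$end, function(e) unit_follows(text, e), logical(1)))
    f1 <- f1[!drop, ]
    add(f1, 1)
  }

  f2 <- scan_pattern(text, P_MIL)
  if (nrow(f2) > 0) {
    ambiguous <- as.integer(f2$raw) >= 1900 & as.integer(f2$raw) <= 2099
    cued <- vapply(f2$start, function(s) {
      str_detect(substr(text, 1, s), regex(P_TIME_CUE_BEFORE,
        ignore_case = TRUE
      ))
    }, logical(1))
    f2 <- f2[!ambiguous | cued, ]
    if (nrow(f2) > 0) {
      fields <- map(f2$raw, parse_clock_token)
      f2 <- tibble(
        start = f2$start, end = f2$end, raw = f2$raw, kind = "military",
        hour = map_int(fields, "hour"), minute = map_int(fields, "minute")
      )
      add(f2, 2)
    }
  }

  f3 <- scan_pattern(text, paste0(
    "\\b(?:since|at|around|about|approx(?:imately)?|until|till)\\s+",
    "(1[0-2]|[1-9])\\b(?![0-9/:.])(?!\\s*(?:a\\.?m|p\\.?m))"
  ))
  if (nrow(f3) > 0) {
    # narrow the span to the numeral itself
    numstart <- f3$end - nchar(f3$g1)
    f3 <- tibble(
      start = as.integer(numstart), end = f3$end, raw = f3$g1,
      kind = "clock_ampm", hour = as.integer(f3$g1), minute = 0L
    )
    if (distractor_guard) {
      f3 <- f3[!vapply(f3$end, function(e) unit_follows(text, e), logical(1)), ]
    }
    add(f3, 3)
  }

  if (length(cands) == 0) {
    return(assign_format_category(te_empty()))
  }
  out <- resolve_overlaps(bind_rows(te_empty(), list_rbind(cands)))
  out$prio <- NULL
  out <- assign_format_category(as_tibble(out))
  validate_expressions(out, text)
}

#' Extract and anchor onset date-times from a clinical note
#'
#' Runs the hybrid pipeline on one note: primary parsing, fallback scanning
#' when the primary pass finds nothing, then anchoring of every expression
#' to the note's date-time through the onset rule set. In `"faithful"` mode
#' every anchored output is emitted in document order with no deduplication
#' (identical outputs may repeat, reproducing the published pipeline's
#' behavior). In `"extended"` mode outputs are deduplicated, candidates
#' anchoring after the note date-time are dropped, the distractor guard is
#' active, and the most-recent-episode rule yields a single resolved onset.
#'
#' @param note A one-row note tibble from [clinical_note()] (or a list with
#'   fields `note_id`, `note_datetime`, `text`).
#' @param mode `"extended"` (default) or `"faithful"`.
#' @param always_fallback Run the fallback scanner even when primary parsing
#'   succeeds (default `FALSE`, matching the published orchestration).
#' @return An `onset_extraction` list: `note_id`, `mode`, `outputs` (a
#'   normalized-onset tibble), `n_outputs`, and in extended mode `resolved`
#'   / `resolved_formatted` (NULL when nothing anchors).
#' @examples
#' note <- clinical_note(
#'   "n1", "TRIAGE", "01/01/2000 08:35",
#'   "pt states symptoms started 1 day ago"
#' )
#' extract_onsets(note)$resolved_formatted
#' @export
extract_onsets <- function(note, mode = c("extended", "faithful"),
                           always_fallback = FALSE) {
  mode <- match.arg(mode)
  guard <- mode == "extended"
  text <- note$text
  note_dt <- note$note_datetime
  prim <- parse_primary(text, note_dt, distractor_guard = guard)
  fb <- te_empty()
  if (nrow(prim) == 0 || always_fallback) {
    fb <- parse_fallback(text, note_dt, distractor_guard = guard)
    if (nrow(prim) > 0 && nrow(fb) > 0) {
      clash <- vapply(seq_len(nrow(fb)), function(i) {
        any(fb$start[i] < prim$end & fb$end[i] > prim$start)
      }, logical(1))
      fb <- fb[!clash, ]
    }
  }
  outputs <- bind_rows(
    anchor_table(prim, note_dt, text, "primary"),
    anchor_table(fb, note_dt, text, "fallback")
  )
  outputs <- outputs[order(outputs$start), ]
  resolved <- NULL
  if (mode == "extended") {
    outputs <- distinct(outputs, .data$formatted, .keep_all = TRUE)
    outputs <- outputs[outputs$onset <= note_dt, ]
    if (nrow(outputs) > 0) {
      resolved <- select_most_recent(outputs$onset, note_dt)
    }
  }
  structure(
    list(
      note_id = note$note_id,
      mode = mode,
      outputs = outputs,
      n_outputs = nrow(outputs),
      resolved = resolved,
      resolved_formatted = if (is.null(resolved)) NULL else format_datetime(resolved)
    ),
    class = "onset_extraction"
  )
}

#' @export
print.onset_extraction <- function(x, ...) {
  cat(sprintf(
    "<onset_extraction> note %s (%s mode): %d output(s)\n",
    x$note_id, x$mode, x$n_outputs
  ))
  if (x$n_outputs > 0) {
    print(x$outputs[c("raw", "stage", "formatted")])
  }
  if (!is.null(x$resolved_formatted)) {
    cat("resolved onset:", x$resolved_formatted, "\n")
  }
  invisible(x)
}
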