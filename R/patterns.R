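# Pattern fragments and low-level scanning machinery shared by the hybrid
# parser and the regex suite. All matching is case-insensitive; spans are
# converted to 0-based half-open on the way out.

P_AMPM <- "(?:a\\.?m\\.?|p\\.?m\\.?)"
# clock with meridiem: "9 pm", "11:30 am", "3AM". Lookbehind keeps the hour
# from starting inside a longer number or a dotted token like "4.45".
P_CLOCK_AMPM <- paste0(
  "(?<![0-9.:])\\b(?:1[0-2]|0?[1-9])(?::[0-5][0-9])?\\s*", P_AMPM, "(?![a-z])"
)
P_HHMM <- "(?<![0-9.:])\\b(?:[01]?[0-9]|2[0-3]):[0-5][0-9](?![.:]?[0-9])"
P_HHMM_NOAMPM <- paste0(P_HHMM, "(?!\\s*", P_AMPM, ")")
P_MIL <- "(?<![0-9])(?:[01][0-9]|2[0-3])[0-5][0-9](?![0-9])"
P_TIME_TOK <- paste0("(?:", P_CLOCK_AMPM, "|", P_HHMM, "|", P_MIL, ")")

P_RELWORD <- paste(
  "(?:last\\s+night|last\\s+evening|this\\s+morning|this\\s+evening",
  "this\\s+afternoon|yesterday|today|tonight|last\\s+week|next\\s+week)",
  sep = "|"
)
P_DAYPART <- paste0(
  "\\b(?:after\\s+lunch|after\\s+dinner|lunch\\s*time|dinner\\s*time|",
  "midmorning|morning|afternoon|evening)\\b"
)
P_WAKE <- paste0(
  "\\b(?:awaken(?:s|ed)?\\s+from\\s+sleep|",
  "(?:(?:he|she|pt|patient)\\s+)?(?:woke|awoke|awakened|wakes?)",
  "(?:\\s+up)?(?:\\s+in\\s+the\\s+morning)?)\\b"
)

P_NUMWORD <- paste0(
  "(?:one|two|three|four|five|six|seven|eight|nine|ten|eleven|twelve|an?)"
)
P_UNIT <- "(?:hours?|hrs?|days?|weeks?|wks?|months?)"
P_OFFSET <- paste0("\\b(\\d{1,3}|", P_NUMWORD, ")\\s+(", P_UNIT, ")\\s+ago\\b")
P_RANGE_SEP <- "\\s*(?:-|–|—|to|or)\\s*"
P_RANGE_AGO <- paste0(
  "\\b(\\d{1,3})", P_RANGE_SEP, "(\\d{1,3})\\s+(", P_UNIT, ")\\s+ago\\b"
)
P_RANGE_EP <- paste0("(?:", P_MIL, "|", P_HHMM, ")")
P_RANGE_CLOCK <- paste0(
  "(", P_RANGE_EP, ")", P_RANGE_SEP, "(", P_RANGE_EP, ")(\\s*", P_AMPM, ")?"
)
P_RANGE_AMPM <- paste0(
  "\\b(1[0-2]|[1-9])", P_RANGE_SEP, "(1[0-2]|[1-9])\\s*(", P_AMPM, ")(?![a-z])"
)

P_MONTH <- paste0(
  "(?:jan(?:uary)?|feb(?:ruary)?|mar(?:ch)?|apr(?:il)?|may|jun(?:e)?|",
  "jul(?:y)?|aug(?:ust)?|sep(?:t(?:ember)?)?|oct(?:ober)?|nov(?:ember)?|",
  "dec(?:ember)?)"
)
P_MONTHDATE <- paste0(
  "\\b(", P_MONTH, ")\\.?\\s+(\\d{1,2})(?:\\s*,\\s*(\\d{4}))?\\b"
)
P_NUMDATE <- paste0(
  "(?<![0-9/])\\b(0?[1-9]|1[0-2])/(0?[1-9]|[12][0-9]|3[01])",
  "(?:/(\\d{4}|\\d{2}))?\\b(?!/)"
)
P_YEAR <- "(?<![0-9/])(?:19[0-9]{2}|20[0-9]{2})(?![0-9/])"
P_BARE_NUM <- "(?<![0-9/:.])\\b(?:1[0-2]|[1-9])\\b(?![0-9/:.])(?!\\s*(?:a\\.?m|p\\.?m))"

# unit/count tokens that mark a bare number as non-temporal (dose, device
# count, age): the distractor guard
P_UNIT_AFTER <- paste0(
  "^\\s*(?:mg|mcg|gm?|ml|cc|mm|cm|l|lpm|units?|stents?|",
  "nitro(?:glycerin)?s?|asa|tabs?|tablets?|pills?|doses?|puffs?|sprays?|",
  "x|times|yo|y/?o|year[- ]old|%)\\b"
)

# time cue that disambiguates a 4-digit 1900-2099 token as military time
P_TIME_CUE_BEFORE <- paste0(
  "(?:\\b(?:at|since|around|about|approx(?:imately)?|until|till|",
  "onset|from)\\s*|@\\s*)$"
)

MONTH_ABBR <- c(
  jan = 1L, feb = 2L, mar = 3L, apr = 4L, may = 5L, jun = 6L,
  jul = 7L, aug = 8L, sep = 9L, oct = 10L, nov = 11L, dec = 12L
)

NUMWORD_VALUES <- c(
  one = 1, two = 2, three = 3, four = 4, five = 5, six = 6, seven = 7,
  eight = 8, nine = 9, ten = 10, eleven = 11, twelve = 12, a = 1, an = 1
)

# locate all case-insensitive matches; returns 0-based half-open spans plus
# capture groups g1, g2, ...
scan_pattern <- function(text, pattern) {
  rx <- regex(pattern, ignore_case = TRUE)
  loc <- str_locate_all(text, rx)[[1]]
  if (nrow(loc) == 0) {
    return(tibble(start = integer(), end = integer(), raw = character()))
  }
  out <- tibble(
    start = loc[, 1] - 1L,
    end = loc[, 2],
    raw = str_sub(text, loc[, 1], loc[, 2])
  )
  grp <- str_match_all(text, rx)[[1]]
  if (ncol(grp) > 1) {
    for (j in 2:ncol(grp)) out[[paste0("g", j - 1)]] <- grp[, j]
  }
  out
}

# greedy non-overlap resolution: strongest priority first, longer match
# breaking ties, then leftmost; result in document order
resolve_overlaps <- function(cands) {
  if (nrow(cands) == 0) {
    return(cands)
  }
  cands <- cands[order(cands$prio, -(cands$end - cands$start), cands$start), ]
  keep <- rep(TRUE, nrow(cands))
  for (i in seq_len(nrow(cands))) {
    if (!keep[i]) next
    if (i < nrow(cands)) {
      later <- (i + 1):nrow(cands)
      clash <- cands$start[later] < cands$end[i] &
        cands$end[later] > cands$start[i]
      keep[later][clash] <- FALSE
    }
  }
  out <- cands[keep, ]
  out[order(out$start), ]
}

# hour/minute/meridiem components of a single clock-like token
parse_clock_token <- function(tok) {
  low <- tolower(tok)
  mer <- str_match(low, "([ap])\\.?m")[, 2]
  mer <- if (is.na(mer)) NA_character_ else paste0(mer, "m")
  hm <- str_match(low, "(\\d{1,2})[:.](\\d{2})")
  if (!is.na(hm[1, 1])) {
    hour <- as.integer(hm[1, 2])
    minute <- as.integer(hm[1, 3])
  } else {
    mil <- str_match(low, "\\b(\\d{2})(\\d{2})\\b")
    if (!is.na(mil[1, 1])) {
      hour <- as.integer(mil[1, 2])
      minute <- as.integer(mil[1, 3])
    } else {
      hour <- as.integer(str_match(low, "(\\d{1,2})")[, 2])
      minute <- 0L
    }
  }
  list(hour = hour, minute = minute, meridiem = mer)
}

# clock-token kind for the shared expression schema
clock_token_kind <- function(tok) {
  low <- tolower(tok)
  if (str_detect(low, "[ap]\\.?m")) {
    "clock_ampm"
  } else if (str_detect(low, ":")) {
    "clock_hhmm"
  } else {
    "military"
  }
}

offset_quantity_value <- function(tok) {
  low <- tolower(str_squish(tok))
  if (str_detect(low, "^\\d+$")) {
    return(as.numeric(low))
  }
  unname(NUMWORD_VALUES[low])
}

offset_unit_value <- function(tok) {
  low <- tolower(tok)
  if (str_starts(low, "h")) {
    "hour"
  } else if (str_starts(low, "d")) {
    "day"
  } else if (str_starts(low, "w")) {
    "week"
  } else {
    "month"
  }
}

# the sentence containing a 0-based offset (context for meridiem inference)
sentence_of <- function(text, start0) {
  bounds <- str_locate_all(text, "[.!?](?=\\s)")[[1]][, 1]
  begin <- if (any(bounds <= start0)) max(bounds[bounds <= start0]) else 0L
  nxt <- bounds[bounds > start0]
  stop_at <- if (length(nxt)) min(nxt) else nchar(text)
  substr(text, begin + 1, stop_at)
}

#' Parse a single temporal token into a time expression
#'
#' Convenience constructor for rule-level operations such as
#' [resolve_range()]: turns one token ("0300", "2:15 pm", "11:30",
#' "2 days ago") into a one-row expression tibble.
#'
#' @param raw A single token string.
#' @return One-row expression tibble (span covers the whole token).
#' @examples
#' time_expr("0300")$kind
#' time_expr("2 days ago")$offset_quantity
#' @export
time_expr <- function(raw) {
  tok <- str_squish(raw)
  n <- nchar(tok)
  off <- str_match(tolower(tok), paste0("^", P_OFFSET, "$"))
  if (!is.na(off[1, 1])) {
    return(te_row(0L, n, tok,
      kind = "relative_offset",
      offset_quantity = offset_quantity_value(off[1, 2]),
      offset_unit = offset_unit_value(off[1, 3])
    ))
  }
  if (str_detect(tok, "^[0-9]{4}$")) {
    ct <- parse_clock_token(tok)
    if (ct$hour <= 23 && ct$minute <= 59) {
      return(te_row(0L, n, tok,
        kind = "military",
        hour = ct$hour, minute = ct$minute
      ))
    }
  }
  if (str_detect(tok, regex("^\\d{1,2}(:[0-5][0-9])?\\s*[ap]\\.?m\\.?$",
    ignore_case = TRUE
  ))) {
    ct <- parse_clock_token(tok)
    return(te_row(0L, n, tok,
      kind = "clock_ampm",
      hour = ct$hour, minute = ct$minute, meridiem = ct$meridiem
    ))
  }
  if (str_detect(tok, "^\\d{1,2}:[0-5][0-9]$")) {
    ct <- parse_clock_token(tok)
    if (ct$hour <= 23) {
      return(te_row(0L, n, tok,
        kind = "clock_hhmm",
        hour = ct$hour, minute = ct$minute
      ))
    }
  }
  abort_onsetdt(
    sprintf("cannot interpret '%s' as a single temporal token", raw),
    "onsetdt_parse_error"
  )
}
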