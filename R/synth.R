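# Seeded generator of synthetic clinical-note sentences with gold onset
# annotations. Templates mimic the short, jargon-heavy register of triage
# and H&P narratives (one onset expression per note, optional distractor
# numerics). Gold values are computed by generator-side arithmetic that
# shares no code with the extraction rules, so extractor-vs-gold agreement
# is a genuine end-to-end check.

SYNTH_FAMILIES <- c(
  "clock_ampm", "hhmm", "military", "daypart", "wake",
  "offset_ago", "range", "hour_rel"
)

#' Configuration for the synthetic corpus generator
#'
#' @param n_notes Number of notes.
#' @param seed Integer seed; the corpus is a pure function of the config.
#' @param category_weights Named non-negative weights over the template
#'   families (`r paste(SYNTH_FAMILIES, collapse = ", ")`); normalized to
#'   sum to 1. Default uniform.
#' @param distractor_rate Probability of inserting a dose/count distractor
#'   sentence ("has had 6 stents in past") alongside the onset expression.
#' @param note_type_mix Named probabilities over note types; defaults to the
#'   H&P / Triage / ED-screening proportions of the 71-note study (49/19/3).
#' @param note_datetime_window Length-2 POSIXct vector bounding sampled note
#'   date-times.
#' @param multi_episode Generate a second onset expression per note to
#'   exercise the most-recent-episode rule (default `FALSE`).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_notes = 200,
                         seed = 1,
                         category_weights = NULL,
                         distractor_rate = 0.25,
                         note_type_mix = c(HP = 49, TRIAGE = 19, ED_SCREEN = 3) / 71,
                         note_datetime_window = c(
                           make_dt(2000, 1, 1, 0, 0),
                           make_dt(2000, 12, 30, 23, 59)
                         ),
                         multi_episode = FALSE) {
  if (is.null(category_weights)) {
    category_weights <- stats::setNames(
      rep(1 / length(SYNTH_FAMILIES), length(SYNTH_FAMILIES)), SYNTH_FAMILIES
    )
  }
  stopifnot(
    all(SYNTH_FAMILIES %in% names(category_weights)),
    all(category_weights >= 0), sum(category_weights) > 0,
    all(note_type_mix >= 0), sum(note_type_mix) > 0,
    distractor_rate >= 0, distractor_rate <= 1
  )
  structure(
    list(
      n_notes = as.integer(n_notes),
      seed = as.integer(seed),
      category_weights = category_weights / sum(category_weights),
      distractor_rate = distractor_rate,
      note_type_mix = note_type_mix / sum(note_type_mix),
      note_datetime_window = note_datetime_window,
      multi_episode = isTRUE(multi_episode)
    ),
    class = "synth_config"
  )
}

# ---- generator-side gold oracle (independent of the extraction rules) ----

# literal copy of the published daypart table; kept separate from the
# shipped lexicon on purpose
G_DAYPART <- c(
  "morning" = 7, "lunch time" = 12, "afternoon" = 15, "dinner time" = 18,
  "evening" = 22, "midmorning" = 9, "after lunch" = 13, "after dinner" = 19
)

# place hh:mm on the note's or previous day by brute-force enumeration
g_place_clock <- function(hh, mm, note_dt) {
  d0 <- as.POSIXct(trunc(note_dt, "days"))
  cands <- c(d0 + hh * 3600 + mm * 60, d0 - 86400 + hh * 3600 + mm * 60)
  cands <- cands[cands <= note_dt]
  max(cands)
}

# ambiguous 12-hour value: enumerate am/pm x today/yesterday, latest <= note
g_place_ambiguous <- function(h12, mm, note_dt) {
  d0 <- as.POSIXct(trunc(note_dt, "days"))
  hours <- c(h12 %% 12, h12 %% 12 + 12)
  cands <- as.POSIXct(c(
    outer(d0 + c(0, -86400), hours * 3600 + mm * 60, `+`)
  ), origin = "1970-01-01", tz = DT_TZ)
  cands <- cands[cands <= note_dt]
  max(cands)
}

# one-step-at-a-time backward walk
g_step_back <- function(note_dt, n_steps, step_seconds) {
  out <- note_dt
  for (i in seq_len(n_steps)) out <- out - step_seconds
  out
}

note_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483647)
}

# ---- templates -----------------------------------------------------------

synth_template <- function(family, note_dt, multi_episode = FALSE) {
  if (multi_episode) {
    k <- sample(1:4, 1)
    text <- sprintf(
      "c/o cp started %d days ago and recurred this morning.", k
    )
    cand1 <- g_step_back(note_dt, k, 86400)
    cand2 <- g_place_clock(7, 0, note_dt)
    return(list(text = text, gold = max(c(cand1, cand2))))
  }
  switch(family,
    clock_ampm = {
      h <- sample(1:12, 1)
      mm <- sample(c(0L, 15L, 30L, 45L), 1)
      mer <- sample(c("am", "pm"), 1)
      form <- sample(1:3, 1)
      tok <- switch(form,
        sprintf("%d:%02d %s", h, mm, mer),
        sprintf("%d %s", h, mer),
        sprintf("%d%s", h, mer)
      )
      if (form != 1) mm <- 0L
      text <- sprintf("c/o substernal cp which began at %s while at home.", tok)
      h24 <- if (mer == "pm") h %% 12 + 12 else h %% 12
      list(text = text, gold = g_place_clock(h24, mm, note_dt))
    },
    hhmm = {
      h <- sample(0:23, 1)
      mm <- sample(0:59, 1)
      text <- sprintf("pt reports chest pressure starting at %d:%02d.", h, mm)
      gold <- if (h == 0 || h >= 13) {
        g_place_clock(h, mm, note_dt)
      } else {
        g_place_ambiguous(h, mm, note_dt)
      }
      list(text = text, gold = gold)
    },
    military = {
      h <- sample(0:23, 1)
      mm <- sample(0:59, 1)
      text <- sprintf("pt reports cp onset %02d%02d.", h, mm)
      list(text = text, gold = g_place_clock(h, mm, note_dt))
    },
    daypart = {
      phrase <- sample(names(G_DAYPART), 1)
      text <- sprintf("c/o cp since %s, denies sob.", phrase)
      list(
        text = text,
        gold = g_place_clock(unname(G_DAYPART[phrase]), 0, note_dt)
      )
    },
    wake = {
      v <- sample(1:3, 1)
      text <- switch(v,
        "pt states he woke with severe chest pressure.",
        "she awoke with cp radiating to left arm.",
        "cp when he woke up in the morning."
      )
      hh <- if (v == 3) 6 else 3
      list(text = text, gold = g_place_clock(hh, 0, note_dt))
    },
    offset_ago = {
      unit <- sample(c("hour", "day", "week"), 1)
      q <- switch(unit,
        hour = sample(2:12, 1),
        day = sample(1:4, 1),
        week = sample(1:5, 1)
      )
      word <- sample(c(TRUE, FALSE), 1)
      qtok <- if (word && q <= 12) {
        c(
          "one", "two", "three", "four", "five", "six", "seven", "eight",
          "nine", "ten", "eleven", "twelve"
        )[q]
      } else {
        as.character(q)
      }
      text <- sprintf(
        "pt describes intermittent cp that started %s %s%s ago.",
        qtok, unit, if (q == 1) "" else "s"
      )
      step <- switch(unit, hour = 3600, day = 86400, week = 7 * 86400)
      list(text = text, gold = g_step_back(note_dt, q, step))
    },
    range = {
      if (sample(c(TRUE, FALSE), 1)) {
        # military clock range: endpoint anchoring closest to the note wins
        h1 <- sample(0:22, 1)
        h2 <- sample((h1 + 1):23, 1)
        mm <- sample(c(0L, 30L), 1)
        sep <- sample(c("-", "–", " to "), 1)
        text <- sprintf(
          "chest pain or pressure began around %02d%02d%s%02d%02d.",
          h1, mm, sep, h2, mm
        )
        cands <- c(
          g_place_clock(h1, mm, note_dt),
          g_place_clock(h2, mm, note_dt)
        )
        list(text = text, gold = max(cands[cands <= note_dt]))
      } else {
        unit <- sample(c("day", "week"), 1)
        a <- sample(1:3, 1)
        b <- a + sample(1:2, 1)
        sep <- sample(c("-", "–", " to "), 1)
        text <- sprintf("cp %d%s%d %ss ago per pt.", a, sep, b, unit)
        step <- if (unit == "day") 86400 else 7 * 86400
        list(text = text, gold = g_step_back(note_dt, a, step))
      }
    },
    hour_rel = {
      v <- sample(1:3, 1)
      if (v == 1) {
        h <- sample(1:12, 1)
        mer <- sample(c("am", "pm"), 1)
        text <- sprintf("cp began %d%s today, ekg in triage.", h, mer)
        h24 <- if (mer == "pm") h %% 12 + 12 else h %% 12
        d0 <- as.POSIXct(trunc(note_dt, "days"))
        cand <- d0 + h24 * 3600
        if (cand > note_dt) cand <- cand - 86400
        list(text = text, gold = cand)
      } else if (v == 2) {
        h <- sample(1:11, 1)
        text <- sprintf("c/o cp which began last night at %d pm.", h)
        d0 <- as.POSIXct(trunc(note_dt, "days"))
        list(text = text, gold = d0 - 86400 + (h + 12) * 3600)
      } else {
        h <- sample(0:23, 1)
        mm <- sample(0:59, 1)
        text <- sprintf("pt noted cp %02d%02d yesterday.", h, mm)
        d0 <- as.POSIXct(trunc(note_dt, "days"))
        list(text = text, gold = d0 - 86400 + h * 3600 + mm * 60)
      }
    },
    abort_onsetdt(paste("unknown template family", family), "onsetdt_schema_error")
  )
}

DISTRACTORS <- c(
  "has had %d stents in past.",
  "given %d mg morphine in ed.",
  "takes asa 81 mg daily.",
  "has taken %d nitro."
)

#' Generate one synthetic note with its gold annotation
#'
#' Deterministic given `(config$seed, index)`. The note text contains
#' exactly one onset expression drawn from a template family (two when
#' `multi_episode`), rendered into a triage/H&P-style sentence, optionally
#' with a distractor numeric sentence. The gold onset is computed by the
#' generator's own calendar arithmetic, independent of the extraction rules.
#'
#' @param config A [synth_config()].
#' @param index Note index (1-based).
#' @return List with `note` (one-row note tibble), `annotation` (one-row
#'   gold tibble), and `meta` (family, distractor span or NA).
#' @export
generate_note <- function(config, index) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(note_seed(config$seed, index), {
    family <- sample(SYNTH_FAMILIES, 1, prob = config$category_weights)
    note_type <- sample(names(config$note_type_mix), 1,
      prob = config$note_type_mix
    )
    win <- as.numeric(config$note_datetime_window)
    note_dt <- trunc_minute(as.POSIXct(
      stats::runif(1, win[1], win[2]),
      origin = "1970-01-01", tz = DT_TZ
    ))
    tmpl <- synth_template(family, note_dt, config$multi_episode)
    text <- tmpl$text
    d_start <- NA_integer_
    d_end <- NA_integer_
    if (stats::runif(1) < config$distractor_rate) {
      dtxt <- sub("%d", sample(2:9, 1), sample(DISTRACTORS, 1), fixed = TRUE)
      if (stats::runif(1) < 0.5) {
        d_start <- 0L
        d_end <- nchar(dtxt)
        text <- paste(dtxt, text)
      } else {
        d_start <- nchar(text) + 1L
        d_end <- d_start + nchar(dtxt)
        text <- paste(text, dtxt)
      }
    }
    list(
      note = clinical_note(
        sprintf("synth-%04d", index), note_type, note_dt, text
      ),
      annotation = tibble(
        note_id = sprintf("synth-%04d", index),
        gold_onset = trunc_minute(tmpl$gold)
      ),
      meta = tibble(
        note_id = sprintf("synth-%04d", index), family = family,
        distractor_start = d_start, distractor_end = d_end
      )
    )
  })
}

#' Generate a synthetic annotated corpus
#'
#' @param config A [synth_config()].
#' @return List of tibbles: `notes` (note_id, note_type, note_datetime,
#'   text), `annotations` (note_id, gold_onset), `meta` (template family and
#'   distractor span per note).
#' @examples
#' corpus <- generate_corpus(synth_config(n_notes = 5, seed = 42))
#' corpus$notes$text
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_notes == 0) {
    return(list(
      notes = clinical_note("x", "HP", make_dt(2000, 1, 1), "")[0, ],
      annotations = tibble(
        note_id = character(),
        gold_onset = as.POSIXct(character(), tz = DT_TZ)
      ),
      meta = tibble(
        note_id = character(), family = character(),
        distractor_start = integer(), distractor_end = integer()
      )
    ))
  }
  parts <- map(seq_len(config$n_notes), function(i) generate_note(config, i))
  list(
    notes = list_rbind(map(parts, "note")),
    annotations = list_rbind(map(parts, "annotation")),
    meta = list_rbind(map(parts, "meta"))
  )
}
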