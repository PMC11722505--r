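triage_sentence <- paste(
  "He was in his usual state of health until approx 3AM today,",
  "when he says he woke and had severe chest discomfort/pressure"
)

test_that("primary parsing detects compound phrases as single expressions", {
  note_dt <- make_dt(2000, 1, 2, 10, 15)
  text <- "c/o cp which began last night at 9 pm while he was watching TV"
  exprs <- parse_primary(text, note_dt)
  expect_equal(nrow(exprs), 1)
  expect_equal(exprs$raw, "last night at 9 pm")
  expect_equal(exprs$hour, 9L)
  expect_equal(exprs$meridiem, "pm")
  expect_equal(exprs$rel_word, "last night")
  expect_equal(exprs$format_category, "HOUR_PLUS_RELATIVE")
  # span invariant: raw recoverable from 0-based half-open offsets
  expect_equal(substr(text, exprs$start + 1, exprs$end), exprs$raw)
})

test_that("primary parsing finds both the explicit time and its wake elaboration", {
  exprs <- parse_primary(triage_sentence, make_dt(2000, 1, 4, 9, 30))
  expect_equal(exprs$raw, c("3AM today", "he woke"))
  expect_equal(exprs$kind, c("clock_ampm", "wake_phrase"))
})

test_that("primary parsing returns nothing on empty or atemporal text", {
  nd <- make_dt(2000, 1, 1, 12, 0)
  expect_equal(nrow(parse_primary("", nd)), 0)
  expect_equal(nrow(parse_primary("pt resting comfortably, no acute distress", nd)), 0)
})

test_that("the distractor guard drops dose/count numerals in extended mode only", {
  nd <- make_dt(2000, 1, 2, 10, 15)
  text <- "has taken 6 nitro since last night. has had 6 stents in past."
  faithful <- parse_primary(text, nd)
  expect_true("6" %in% faithful$raw)
  guarded <- parse_primary(text, nd, distractor_guard = TRUE)
  expect_false("6" %in% guarded$raw)
  expect_true("last night" %in% guarded$raw)
})

test_that("fallback captures dotted explicit times that primary misses", {
  nd <- make_dt(2000, 1, 3, 11, 0)
  text <- "66 y/o male presents to SMH ED with complains of chest pain since morning 4.45 am"
  expect_equal(nrow(parse_primary(text, nd)), 0)
  fb <- parse_fallback(text, nd)
  expect_equal(nrow(fb), 1)
  expect_equal(fb$raw, "4.45 am")
  expect_equal(correct_time_punctuation(fb$raw), "4:45 am")
  expect_equal(fb$hour, 4L)
  expect_equal(fb$minute, 45L)
  expect_equal(fb$meridiem, "am")
})

test_that("punctuation correction touches only clock-shaped tokens", {
  expect_equal(correct_time_punctuation("4.45 am"), "4:45 am")
  expect_equal(correct_time_punctuation("4:45 am"), "4:45 am")
  expect_equal(correct_time_punctuation("4.5 mg"), "4.5 mg")
  expect_equal(correct_time_punctuation("12.30"), "12:30")
})

test_that("fallback infers the meridiem of a cue-marked bare hour from context", {
  nd <- make_dt(2000, 1, 5, 23, 0)
  text <- "pain since 7 this evening per pt"
  fb <- parse_fallback(text, nd)
  expect_equal(fb$raw[1], "7")
  # daypart context pushes the bare hour into the evening half of the day
  expect_equal(infer_meridiem(fb$hour[1], 0, text, nd), 19L)
  out <- anchor_regex_outputs(fb[1, ], nd, mode = "extended", text = text)
  expect_equal(out$formatted, "01/05/2000 19:00")
})

test_that("meridiem inference prefers daypart cues, else the latest anchor before the note", {
  # daypart cue wins
  expect_equal(infer_meridiem(4, 0, "since morning", make_dt(2000, 1, 1, 10, 0)), 4L)
  expect_equal(infer_meridiem(4, 0, "this evening", make_dt(2000, 1, 1, 10, 0)), 16L)
  # 24-hour values bypass inference
  expect_equal(infer_meridiem(13, 0, "", make_dt(2000, 1, 1, 10, 0)), 13L)
  # no cues: enumerate {am,pm} x {today,yesterday}, latest <= note wins
  nd <- make_dt(2000, 1, 2, 6, 0)
  expect_equal(infer_meridiem(7, 0, "", nd), 19L)
  # brute-force agreement over random configurations
  set.seed(31)
  for (i in 1:50) {
    nd <- random_dts(1)
    h <- sample(1:12, 1)
    got <- infer_meridiem(h, 0, "", nd)
    d0 <- lubridate::floor_date(nd, "day")
    cands <- c(
      d0 + (h %% 12) * 3600, d0 + (h %% 12 + 12) * 3600,
      d0 - 86400 + (h %% 12) * 3600, d0 - 86400 + (h %% 12 + 12) * 3600
    )
    best <- max(cands[cands <= nd])
    expect_equal(got, as.integer(lubridate::hour(best)))
  }
})

test_that("faithful extraction reproduces the duplicate-output failure mode", {
  note <- clinical_note("t1", "TRIAGE", make_dt(2000, 1, 4, 9, 30), triage_sentence)
  res <- extract_onsets(note, mode = "faithful")
  expect_equal(res$n_outputs, 2)
  expect_equal(res$outputs$formatted[1], res$outputs$formatted[2])
  expect_equal(res$outputs$formatted[1], "01/04/2000 03:00")
  expect_equal(res$outputs$stage, c("primary", "lexicon"))
})

test_that("extended extraction deduplicates and resolves a single onset", {
  note <- clinical_note("t1", "TRIAGE", make_dt(2000, 1, 4, 9, 30), triage_sentence)
  res <- extract_onsets(note, mode = "extended")
  expect_equal(res$n_outputs, 1)
  expect_equal(res$resolved_formatted, "01/04/2000 03:00")
})

test_that("extraction of an empty note yields zero outputs", {
  note <- clinical_note("e", "HP", make_dt(2000, 1, 1, 12, 0), "")
  res <- extract_onsets(note, mode = "faithful")
  expect_equal(res$n_outputs, 0)
  expect_null(extract_onsets(note, mode = "extended")$resolved)
})

test_that("outputs appear in document order of their source spans", {
  note <- clinical_note(
    "o", "HP", make_dt(2000, 3, 10, 14, 0),
    "woke at 2:30 yesterday, cp again this morning"
  )
  res <- extract_onsets(note, mode = "faithful")
  expect_equal(res$outputs$start, sort(res$outputs$start))
})

test_that("partial dates take the note year, stepping back when in the future", {
  note_dt <- make_dt(2000, 2, 10, 9, 0)
  res <- extract_onsets(
    clinical_note("p", "HP", note_dt, "cp intermittently since 03/20"),
    mode = "faithful"
  )
  expect_equal(res$outputs$formatted, "03/20/1999 00:00")
  res2 <- extract_onsets(
    clinical_note("p", "HP", note_dt, "cp since 01/20"),
    mode = "faithful"
  )
  expect_equal(res2$outputs$formatted, "01/20/2000 00:00")
})

test_that("extended-mode resolved onsets never postdate the note", {
  texts <- c(
    "cp started 3 days ago", "c/o cp since evening", "pain at 11:30 pm",
    "began around 0200-0300", "cp 9 pm last night", "next week follow up",
    "he woke with cp", "cp since morning"
  )
  set.seed(17)
  for (t in texts) {
    for (r in 1:5) {
      nd <- random_dts(1)
      res <- extract_onsets(clinical_note("x", "TRIAGE", nd, t), mode = "extended")
      if (!is.null(res$resolved)) expect_lte(as.numeric(res$resolved), as.numeric(nd))
      if (nrow(res$outputs) > 0) expect_true(all(res$outputs$onset <= nd))
    }
  }
})
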