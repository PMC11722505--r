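test_that("the rule lexicon contains every published phrase with its clock time", {
  lex <- onset_lexicon()
  expected <- tibble::tribble(
    ~phrase, ~hour, ~minute, ~source,
    "morning", 7L, 0L, "AHA",
    "lunch time", 12L, 0L, "AHA",
    "afternoon", 15L, 0L, "AHA",
    "dinner time", 18L, 0L, "AHA",
    "evening", 22L, 0L, "AHA",
    "awaken from sleep", 3L, 0L, "AHA",
    "midmorning", 9L, 0L, "EXTENDED",
    "wake up in the morning", 6L, 0L, "EXTENDED",
    "after lunch", 13L, 0L, "EXTENDED",
    "after dinner", 19L, 0L, "EXTENDED"
  )
  expect_equal(
    dplyr::arrange(lex, phrase),
    dplyr::arrange(expected, phrase)
  )
  expect_equal(anyDuplicated(lex$phrase), 0L)
})

test_that("daypart lookup is case- and whitespace-insensitive", {
  expect_equal(lookup_daypart("morning"), list(hour = 7L, minute = 0L))
  expect_equal(lookup_daypart("midmorning"), list(hour = 9L, minute = 0L))
  expect_equal(lookup_daypart("AWAKEN FROM SLEEP"), list(hour = 3L, minute = 0L))
  expect_equal(lookup_daypart("  Lunch   Time "), list(hour = 12L, minute = 0L))
  expect_null(lookup_daypart("while driving"))
})

test_that("wake-verb variants map to the sleep or morning wake rule", {
  for (p in c("he woke", "awoke", "she awakened", "pt woke up")) {
    expect_equal(lookup_daypart(p)$hour, 3L, info = p)
  }
  expect_equal(lookup_daypart("woke up in the morning")$hour, 6L)
  expect_equal(lookup_daypart("wake up in the morning")$hour, 6L)
})

test_that("relative offsets step backward preserving clock time", {
  note <- make_dt(2000, 1, 1, 8, 35)
  expect_equal(
    resolve_relative_offset(1, "day", note),
    make_dt(1999, 12, 31, 8, 35)
  )
  expect_equal(resolve_relative_offset(0, "day", note), note)
  expect_equal(
    resolve_relative_offset(3, "week", make_dt(2000, 1, 22, 10, 0)),
    oracle_step_days(make_dt(2000, 1, 22, 10, 0), 21)
  )
  expect_equal(
    resolve_relative_offset(4, "hour", make_dt(2000, 1, 1, 2, 0)),
    make_dt(1999, 12, 31, 22, 0)
  )
  expect_error(
    resolve_relative_offset(200 * 365, "day", note),
    class = "onsetdt_range_error"
  )
})

test_that("day offsets agree with a one-day-at-a-time stepping oracle", {
  set.seed(99)
  anchors <- random_dts(100)
  for (i in seq_along(anchors)) {
    for (k in c(0:10, sample(11:60, 5))) {
      expect_equal(
        resolve_relative_offset(k, "day", anchors[i]),
        oracle_step_days(anchors[i], k)
      )
    }
  }
})

test_that("hour offsets agree with minute-count arithmetic", {
  set.seed(7)
  anchors <- random_dts(25)
  for (i in seq_along(anchors)) {
    k <- sample(0:72, 1)
    expect_equal(
      resolve_relative_offset(k, "hour", anchors[i]),
      oracle_step_hours(anchors[i], k)
    )
  }
})

test_that("month offsets clamp the day of month", {
  expect_equal(
    resolve_relative_offset(1, "month", make_dt(2000, 3, 31, 9, 0)),
    make_dt(2000, 2, 29, 9, 0)
  )
})

test_that("range resolution keeps the endpoint nearest to the note", {
  note <- make_dt(2000, 1, 1, 9, 0)
  expect_equal(resolve_range("0200", "0300", note)$raw, "0300")
  expect_equal(resolve_range("2 days ago", "3 days ago", note)$raw, "2 days ago")
  expect_equal(
    resolve_range("3 weeks ago", "5 weeks ago", note)$offset_quantity, 3
  )
  expect_equal(resolve_range("0300", "0300", note)$raw, "0300")
})

test_that("range resolution never anchors after the note date-time", {
  set.seed(21)
  anchors <- random_dts(40)
  for (i in seq_along(anchors)) {
    h <- sort(sample(0:23, 2))
    chosen <- resolve_range(
      sprintf("%02d00", h[1]), sprintf("%02d30", h[2]), anchors[i]
    )
    expect_lte(as.numeric(attr(chosen, "onset")), as.numeric(anchors[i]))
  }
})

test_that("most-recent selection equals a brute-force max filter", {
  note <- make_dt(1999, 12, 31, 8, 0)
  expect_equal(
    select_most_recent(
      c(make_dt(1999, 12, 30, 21, 0), make_dt(1999, 12, 31, 3, 0)), note
    ),
    make_dt(1999, 12, 31, 3, 0)
  )
  expect_equal(select_most_recent(make_dt(1999, 12, 30, 1, 1), note),
    make_dt(1999, 12, 30, 1, 1))
  set.seed(5)
  cands <- random_dts(50)
  got <- select_most_recent(cands, make_dt(2001, 1, 1, 0, 0))
  brute <- cands[cands <= make_dt(2001, 1, 1, 0, 0)]
  brute <- brute[order(as.numeric(brute), decreasing = TRUE)][1]
  expect_equal(got, brute)
  expect_error(
    select_most_recent(make_dt(2002, 1, 1), make_dt(2001, 1, 1)),
    class = "onsetdt_flagged_error"
  )
})
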