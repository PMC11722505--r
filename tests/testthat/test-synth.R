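test_that("note generation is deterministic given seed and index", {
  cfg <- synth_config(n_notes = 10, seed = 7)
  a <- generate_note(cfg, 1)
  b <- generate_note(cfg, 1)
  expect_identical(a, b)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1, c2)
  # different seed, different corpus
  c3 <- generate_corpus(synth_config(n_notes = 10, seed = 8))
  expect_false(identical(c1$notes$text, c3$notes$text))
})

test_that("an empty corpus still has the full table schemas", {
  corpus <- generate_corpus(synth_config(n_notes = 0, seed = 1))
  expect_equal(nrow(corpus$notes), 0)
  expect_equal(
    names(corpus$notes),
    c("note_id", "note_type", "note_datetime", "text")
  )
  expect_equal(names(corpus$annotations), c("note_id", "gold_onset"))
})

test_that("family counts stay within binomial bounds under uniform weights", {
  cfg <- synth_config(n_notes = 200, seed = 12, distractor_rate = 0)
  corpus <- generate_corpus(cfg)
  counts <- table(factor(corpus$meta$family, levels = names(cfg$category_weights)))
  p <- 1 / length(cfg$category_weights)
  sigma <- sqrt(200 * p * (1 - p))
  expect_true(all(abs(counts - 200 * p) <= 3 * sigma))
})

test_that("a degenerate mixture emits only the selected family", {
  w <- stats::setNames(numeric(8), c(
    "clock_ampm", "hhmm", "military", "daypart", "wake",
    "offset_ago", "range", "hour_rel"
  ))
  w["military"] <- 1
  corpus <- generate_corpus(synth_config(
    n_notes = 25, seed = 3,
    category_weights = w, distractor_rate = 0
  ))
  expect_true(all(corpus$meta$family == "military"))
  expect_true(all(grepl("onset [0-9]{4}\\.", corpus$notes$text)))
})

test_that("gold onsets agree with oracle arithmetic for offset templates", {
  # the gold for a k-days-ago note equals stepping back k single days
  cfg <- synth_config(n_notes = 50, seed = 44, distractor_rate = 0)
  corpus <- generate_corpus(cfg)
  idx <- which(corpus$meta$family == "offset_ago")
  expect_gt(length(idx), 0)
  for (i in idx) {
    txt <- corpus$notes$text[i]
    m <- regmatches(txt, regexec("started ([a-z0-9]+) (hour|day|week)s? ago", txt))[[1]]
    q <- suppressWarnings(as.integer(m[2]))
    if (is.na(q)) {
      q <- match(m[2], c(
        "one", "two", "three", "four", "five", "six",
        "seven", "eight", "nine", "ten", "eleven", "twelve"
      ))
    }
    step <- c(hour = 3600, day = 86400, week = 7 * 86400)[[m[3]]]
    expected <- corpus$notes$note_datetime[i]
    for (s in seq_len(q)) expected <- expected - step
    expect_equal(corpus$annotations$gold_onset[i], expected, info = txt)
  }
})

test_that("distractor insertion leaves the gold annotation unchanged", {
  base <- synth_config(n_notes = 1, seed = 555, distractor_rate = 0)
  with_d <- synth_config(n_notes = 1, seed = 555, distractor_rate = 1)
  a <- generate_note(base, 1)
  b <- generate_note(with_d, 1)
  expect_equal(a$annotation$gold_onset, b$annotation$gold_onset)
  expect_false(is.na(b$meta$distractor_start))
  d <- substr(b$note$text, b$meta$distractor_start + 1, b$meta$distractor_end)
  expect_match(d, "stents|mg|nitro")
})

test_that("extended extraction recovers every gold onset on a supported-template corpus", {
  cfg <- synth_config(n_notes = 200, seed = 11, distractor_rate = 0)
  corpus <- generate_corpus(cfg)
  hits <- vapply(seq_len(nrow(corpus$notes)), function(i) {
    res <- extract_onsets(corpus$notes[i, ], mode = "extended")
    !is.null(res$resolved) &&
      identical(
        format_datetime(res$resolved),
        format_datetime(corpus$annotations$gold_onset[i])
      )
  }, logical(1))
  expect_equal(sum(hits), 200)
})

test_that("no extractor output overlaps a distractor span at distractor_rate = 1", {
  cfg <- synth_config(n_notes = 100, seed = 77, distractor_rate = 1)
  corpus <- generate_corpus(cfg)
  for (i in seq_len(nrow(corpus$notes))) {
    res <- extract_onsets(corpus$notes[i, ], mode = "extended")
    m <- corpus$meta[i, ]
    if (nrow(res$outputs) > 0 && !is.na(m$distractor_start)) {
      overlap <- res$outputs$start < m$distractor_end &
        res$outputs$end > m$distractor_start
      expect_false(any(overlap), info = corpus$notes$text[i])
    }
  }
})

test_that("multi-episode notes resolve to the most recent episode", {
  cfg <- synth_config(n_notes = 20, seed = 9, distractor_rate = 0, multi_episode = TRUE)
  corpus <- generate_corpus(cfg)
  for (i in seq_len(nrow(corpus$notes))) {
    res <- extract_onsets(corpus$notes[i, ], mode = "extended")
    expect_gte(res$n_outputs, 2)
    expect_equal(
      format_datetime(res$resolved),
      format_datetime(corpus$annotations$gold_onset[i]),
      info = corpus$notes$text[i]
    )
  }
})
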