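test_that("the six families detect the documented expression shapes", {
  got <- extract_expressions_regex(
    "C/o midsternal chest pain radiating to right arm and neck since 0530 today"
  )
  expect_equal(got$raw, "0530 today")
  expect_equal(got$format_category, "HOUR_PLUS_RELATIVE")

  expect_equal(
    extract_expressions_regex("ekg done at 20:30")$format_category, "HHMM_COLON"
  )
  expect_equal(
    extract_expressions_regex("CABG in 2004")$format_category, "YYYY"
  )
  expect_equal(nrow(extract_expressions_regex("no temporal content")), 0)
  expect_equal(nrow(extract_expressions_regex("")), 0)
})

test_that("format categorization matches the published category rows", {
  cases <- list(
    list("pain at 11:30 am", "HH_AMPM", "11:30 am"),
    list("onset 0045 per ems", "MILITARY", "0045"),
    list("cp 9 pm last night", "HOUR_PLUS_RELATIVE", "9 pm last night"),
    list("cp started 01:30", "HHMM_COLON", "01:30"),
    list("stent placed 2008", "YYYY", "2008"),
    list("cp this morning", "OTHER", "this morning"),
    list("worse since the afternoon", "OTHER", "afternoon")
  )
  for (cs in cases) {
    got <- extract_expressions_regex(cs[[1]])
    expect_equal(categorize_format(got), cs[[2]], info = cs[[1]])
    expect_equal(got$raw, cs[[3]], info = cs[[1]])
  }
})

test_that("matches never overlap and arrive in document order", {
  texts <- c(
    "cp 2200 yesterday, again 3am today, ekg at 20:30, CABG in 2004",
    "11:30 pm last night then 0315 today and 4am",
    "on Mar 2, 2016 and Jan 3 at 10 pm"
  )
  for (t in texts) {
    got <- extract_expressions_regex(t)
    expect_gt(nrow(got), 0)
    expect_equal(got$start, sort(got$start))
    if (nrow(got) > 1) {
      expect_true(all(got$start[-1] >= got$end[-nrow(got)]), info = t)
    }
    expect_true(all(categorize_format(got) %in% c(
      "HHMM_COLON", "HH_AMPM", "MILITARY", "HOUR_PLUS_RELATIVE", "YYYY", "OTHER"
    )))
  }
})

test_that("combined time+relative strings are counted once, not split", {
  got <- extract_expressions_regex("cp began 2200 yesterday")
  expect_equal(got$raw, "2200 yesterday")
  expect_equal(nrow(got), 1)
})

test_that("year candidates require a 1900-2099 window and a digit boundary", {
  expect_equal(extract_expressions_regex("CABG in 2004")$kind, "year")
  expect_equal(nrow(extract_expressions_regex("ID 32004 on chart")), 0)
  # a time cue reads an ambiguous token as military time instead
  got <- extract_expressions_regex("cp started at 2030 per pt")
  expect_equal(got$kind, "military")
  expect_equal(got$hour, 20L)
})

test_that("faithful anchoring emits no canonical outputs for any input", {
  nd <- make_dt(2000, 1, 5, 9, 0)
  texts <- c(
    "since 0530 today", "at 11:30 am", "cp 2 days ago", "CABG in 2004", ""
  )
  for (t in texts) {
    exprs <- extract_expressions_regex(t)
    expect_equal(nrow(anchor_regex_outputs(exprs, nd, mode = "faithful")), 0)
  }
})

test_that("extended anchoring resolves expressions through the rule set", {
  nd <- make_dt(2000, 1, 5, 9, 0)
  exprs <- extract_expressions_regex(
    "C/o midsternal chest pain since 0530 today"
  )
  out <- anchor_regex_outputs(exprs, nd, mode = "extended")
  expect_equal(out$formatted, "01/05/2000 05:30")
})
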