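Package: onsetdt
Title: Extract and Normalize Symptom Onset Date-Times from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based extraction and normalization of the date and time of
    patient-reported symptom onset from free-text clinical notes, anchored to
    each note's timestamp. Implements two pipelines: a hybrid natural-language
    date-time parser with an explicit-time fallback scanner, and a suite of six
    case-insensitive regular-expression families. Includes the American Heart
    Association derived rules for unspecified onset times (daypart and wake
    lexicon, relative-offset arithmetic, time-range resolution, most-recent
    episode selection), a match-based evaluation harness, and a seeded
    generator of synthetic annotated clinical sentences for testing without
    protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
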