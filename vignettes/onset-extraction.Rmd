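---
title: "Extracting symptom onset date-times from clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting symptom onset date-times from clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsetdt)
```

## The problem

In acute coronary syndrome the interval between symptom onset and hospital
presentation carries prognostic information, but the onset time usually
lives only in free-text narrative: *"c/o cp which began last night at 9 pm"*,
*"chest pain since morning 4.45 am"*, *"began around 0200–0300"*. `onsetdt`
detects such temporal expressions in a note, normalizes them against the
note's own timestamp (the *reference date-time*), and renders each candidate
onset in the canonical `MM/DD/YYYY HH:MM` format used for exact-match
evaluation against expert annotation.

Two extraction pipelines are implemented, deliberately kept separate:

* **Hybrid parser** (`extract_onsets()`): a primary recognizer for
  human-readable phrases — relative words ("yesterday", "last night"),
  backward offsets ("2 days ago", "four hours ago"), clock times with
  meridiem, compound phrases ("last night at 9 pm"), partial dates
  ("03/20"), and the daypart/wake trigger lexicon — with a fallback scanner
  for explicit numeric times ("4:45 am", "0530", cue-marked bare hours) that
  runs only when the primary pass finds nothing.
* **Regex suite** (`extract_expressions_regex()`): six case-insensitive
  pattern families (HH:MM clock, hour + am/pm, 4-digit military time,
  hour + relative-word combination, dates, standalone relative words and
  years), applied longest-match-first with family order 4 > 1 > 2 > 3 >
  5 > 6 so that "0530 today" stays one expression instead of splitting into
  a military time plus a relative word.

## The rule set for unspecified times

When a note gives only a vague period, a fixed clock time is assigned,
following the AHA key data elements for chest pain plus four extended rows
(shipped as `inst/extdata/onset_lexicon.tsv`, editable without code
changes):

| phrase | time | source |
|---|---|---|
| morning | 07:00 | AHA |
| lunch time | 12:00 | AHA |
| afternoon | 15:00 | AHA |
| dinner time | 18:00 | AHA |
| evening | 22:00 | AHA |
| awaken from sleep | 03:00 | AHA |
| midmorning | 09:00 | extended |
| wake up in the morning | 06:00 | extended |
| after lunch | 13:00 | extended |
| after dinner | 19:00 | extended |

Three further rules complete the set:

* `resolve_relative_offset(q, unit, note_dt)` — "*k* days ago" keeps the
  note's clock time and steps back *k* × 24 h; weeks are seven days; hours
  are exact 60-minute steps. Month offsets (an extension beyond the
  published rules, provided for robustness) use calendar-month arithmetic
  with day-of-month clamping, so one month before March 31 is February 29
  in a leap year.
* `resolve_range(a, b, note_dt)` — a range ("0200–0300", "2–3 days ago")
  is treated as an intermittent symptom and resolved to the endpoint whose
  anchored value is closest to, and not after, the note date-time: the
  later clock time, or the smaller offset. Recognized connectors: hyphen,
  en dash, "to", "or".
* `select_most_recent(candidates, note_dt)` — with several candidate
  onsets, the most recent one at or before the note date-time wins.

## Anchoring assumptions

Everything rests on one clinical assumption: **onset precedes
presentation**. A clock time is placed on the note's calendar day when that
keeps it at or before the note date-time, otherwise on the previous day.
Specific placements:

* "last night" + a pm time → previous day; + an am time → the note's day
  when that is not in the future (the early hours of "last night" belong to
  the note's own date), else the previous day. "last night" alone maps to
  the evening rule, 22:00 on the previous day; "tonight"/"this evening"
  likewise map to 22:00 with the standard day rule.
* "yesterday" alone is a 1-day offset; "today" a 0-day offset. "yesterday"
  combined with a clock time always means the previous calendar day.
* Partial dates ("03/20") take the note's year, stepping back one year when
  that would land in the future; month-name dates without a year behave the
  same; years alone anchor to January 1 00:00.
* A "today"-anchored time later than the note's clock time is shifted one
  day back and **flagged** (`flagged` column) rather than silently accepted
  — the text contradicts the onset-precedes-note assumption and deserves
  review.

**Meridiem inference** (`infer_meridiem()`): hours 0 and 13–23 are already
unambiguous. For 1–12 without am/pm, a daypart cue in the same sentence
decides the half of day (wake verbs and "morning" words → am; afternoon /
evening / night / meal words → pm). With no cue, the am and pm candidates
are both placed by the day rule and the latest anchor not after the note
wins — the most-recent principle applied to ambiguity.

## Faithful versus extended mode

`mode = "faithful"` reproduces the behavior of off-the-shelf parsing as
documented for this task, including its failure modes: bare numerals such
as doses or device counts ("6 mg", "6 stents") can be misread as times, and
a wake phrase that merely elaborates an explicit time ("until approx 3AM
today, when he says he woke") yields a second, duplicate output. No
deduplication is performed. The regex pipeline in faithful mode emits **no**
canonical-format outputs at all — it detects expressions but never anchored
`MM/DD/YYYY HH:MM` strings, matching how the original suite behaved.

`mode = "extended"` is the corrected pipeline: a distractor guard discards
bare numerals followed by unit/count tokens (mg, mcg, stents, nitro, tabs,
times, y/o, …), outputs are deduplicated, candidates anchoring after the
note are dropped, and the most-recent rule condenses the remainder to a
single `resolved` onset. `anchor_regex_outputs(..., mode = "extended")`
gives the regex pipeline the same anchoring machinery.

One orchestration subtlety: the fallback scanner runs only when the primary
pass finds nothing (an `always_fallback` flag overrides). A daypart trigger
immediately followed by a dotted clock token ("…since morning 4.45 am") is
suppressed in the primary grammar — the daypart there elaborates an
explicit time the primary grammar does not cover, and suppressing it lets
the note fall through to the fallback, which owns punctuation correction
("4.45" → "4:45") and captures the precise time instead of the vague 07:00.

## Numerical and representational choices

* Date-times are timezone-naive at minute precision; internally POSIXct in
  UTC (no DST, so day arithmetic in seconds is exact). Seconds are
  truncated, never rounded.
* Canonical-format parsing is strict (zero-padded) by default because
  evaluation is exact string match; `strict = FALSE` covers ingestion of
  hand-typed tables.
* Character spans are 0-based half-open, so `substr(text, start + 1, end)`
  recovers the matched string exactly.
* Overlap resolution is deterministic: hybrid candidates are ranked by
  construct specificity (compounds > ranges > offsets > clocks > dates >
  wake > relative words > dayparts > bare numerals), the regex suite by
  length then family order; ties break leftmost.
* Ambiguous 4-digit tokens in 1900–2099 ("2004", "2030") read as years
  unless a time cue precedes ("at 2030") or a relative word follows
  ("2200 yesterday").
* Offsets landing before the year 1900 raise a range error; ranges where
  neither endpoint anchors at or before the note, and candidate sets that
  are entirely in the future, raise flagged-result errors rather than
  guessing.

Where the published rules were open-ended we fixed a behavior once: the
days-ago rule is applied uniformly for any count (not just 1–4), with
offsets beyond 30 days still resolved by the same arithmetic; "tonight" and
"last night" inherit the evening rule's 22:00; gold annotations are assumed
to be minute-precision throughout.

## The synthetic corpus

Real notes of this kind are IRB-protected, so testing uses
`generate_corpus(synth_config(...))`: seeded, deterministic sentences in
clinical register ("c/o cp since midmorning, denies sob.") each containing
exactly one onset expression from eight template families — clock + am/pm,
HH:MM, military, daypart word, wake phrase, days/weeks/hours-ago, range,
and hour + relative word — with optional distractor sentences ("has had 6
stents in past"). Defaults: 200 notes, uniform family weights, distractor
rate 0.25, note-type mix 49:19:3 (H&P : Triage : ED screening, the
composition of the motivating 71-note collection), note timestamps drawn
from calendar year 2000. A `multi_episode` flag emits two expressions per
note to exercise the most-recent rule.

Gold onsets are computed by generator-side arithmetic that shares no code
with the extraction rules (literal daypart table, one-step-at-a-time
backward walks, brute-force candidate enumeration for ambiguous hours), so
extractor-versus-gold agreement is a genuine end-to-end check. The test
suite verifies 100% gold recovery in extended mode on a 200-note
supported-template corpus, zero distractor-span outputs at distractor rate
1, and binomially plausible family counts; those problem sizes (200/100/60
notes) keep the whole suite under a minute while leaving binomial bounds
meaningful.

What the generator does **not** emulate: full note structure (sections,
headers), length and vocabulary variation of real narratives, misspellings,
negated or hypothetical temporal mentions, and multi-sentence temporal
coreference. Passing on synthetic data therefore demonstrates that the
rules and anchoring are implemented correctly — not that the pipelines
reach any particular accuracy on real clinical notes, where reported
performance of this family of methods is roughly one correctly matched
note in two for the hybrid approach and none in canonical format for the
regex suite.

## Known limitations

* Exact-match evaluation is unforgiving: a pipeline output one minute off
  is counted unmatched (a `tolerance_min` option exists, off by default).
* The distractor guard is a token list, not a model; unusual dose units
  will slip through.
* Negation and hypotheticals ("denies cp last night") are not handled; the
  expression is still extracted.
* Month offsets and >4-day offsets extend the published rule table; they
  are documented as extensions and flagged nowhere else.
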