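# Daypart / wake-phrase lexicon: fixed clock times assigned to vague onset
# periods, following the AHA key data elements for chest pain plus four
# extended rows. Shipped as a plain-text table so users can extend it.

the <- new.env(parent = emptyenv())

#' The unspecified-onset-time rule lexicon
#'
#' Fixed clock times for vague onset phrases: the six AHA-recommended rows
#' (morning 07:00, lunch time 12:00, afternoon 15:00, dinner time 18:00,
#' evening 22:00, awaken from sleep 03:00) plus four extended rows
#' (midmorning 09:00, wake up in the morning 06:00, after lunch 13:00,
#' after dinner 19:00).
#'
#' @param path Optional path to an alternative lexicon table (TSV with
#'   columns `phrase`, `time` as `HH:MM`, `source` in `AHA`/`EXTENDED`).
#' @return A tibble with columns `phrase`, `hour`, `minute`, `source`.
#' @examples
#' onset_lexicon()
#' @export
onset_lexicon <- function(path = NULL) {
  if (is.null(path) && !is.null(the$lexicon)) {
    return(the$lexicon)
  }
  cache <- is.null(path)
  path <- path %||% system.file("extdata", "onset_lexicon.tsv",
    package = "onsetdt", mustWork = TRUE
  )
  lex <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character())
  )
  stopifnot(all(c("phrase", "time", "source") %in% names(lex)))
  hm <- str_match(lex$time, "^([0-2][0-9]):([0-5][0-9])$")
  lex <- tibble(
    phrase = str_squish(tolower(lex$phrase)),
    hour = as.integer(hm[, 2]),
    minute = as.integer(hm[, 3]),
    source = lex$source
  )
  if (cache) the$lexicon <- lex
  lex
}

# wake verbs with no "morning" context fall under the awaken-from-sleep rule
RX_WAKE_VERB <- "\\b(?:woke|awoke|awaken(?:ed|s)?|wakes?)\\b"

#' Look up the rule clock time for a vague onset phrase
#'
#' Case-insensitive, whitespace-normalized lookup against [onset_lexicon()].
#' Wake-verb variants ("woke", "awoke", "he woke up", "awakened") with no
#' morning context map to the awaken-from-sleep rule (03:00); wake phrases
#' mentioning "morning" map to the wake-up-in-the-morning rule (06:00).
#'
#' @param phrase Character phrase (single string).
#' @return A list with `hour` and `minute`, or `NULL` when no rule matches.
#' @examples
#' lookup_daypart("morning")
#' lookup_daypart("AWAKEN FROM SLEEP")
#' lookup_daypart("while driving")
#' @export
lookup_daypart <- function(phrase) {
  key <- str_squish(tolower(phrase))
  lex <- onset_lexicon()
  hit <- which(lex$phrase == key)
  if (length(hit) == 1) {
    return(list(hour = lex$hour[hit], minute = lex$minute[hit]))
  }
  if (str_detect(key, RX_WAKE_VERB)) {
    if (str_detect(key, "\\bmorning\\b")) {
      return(list(hour = 6L, minute = 0L))
    }
    return(list(hour = 3L, minute = 0L))
  }
  NULL
}
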