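# Match-based evaluation: exact comparison of canonical-format outputs
# against expert gold annotations, plus the two tabulations used to report
# results (a note-type x matched x output-count grid and a format-category
# table with example strings).

#' Read gold onset annotations
#'
#' @param path Delimiter-separated file with columns `note_id` and
#'   `gold_onset` (canonical `MM/DD/YYYY HH:MM`).
#' @return Tibble with `note_id` (character) and `gold_onset` (POSIXct).
#' @export
read_annotations_table <- function(path) {
  ann <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character())
  )
  missing <- setdiff(c("note_id", "gold_onset"), names(ann))
  if (length(missing) > 0) {
    abort_onsetdt(
      paste("annotation table missing column(s):", paste(missing, collapse = ", ")),
      "onsetdt_schema_error"
    )
  }
  if (anyDuplicated(ann$note_id)) {
    abort_onsetdt(
      "more than one annotation for the same note_id",
      "onsetdt_schema_error"
    )
  }
  tibble(
    note_id = ann$note_id,
    gold_onset = parse_datetime(ann$gold_onset, strict = FALSE)
  )
}

#' Match one extraction result against its gold annotation
#'
#' A note is matched (1) when any output's canonical formatted string equals
#' the canonical rendering of the gold onset; multiple matching outputs
#' still count as one match. With `tolerance_min > 0` semantic closeness
#' within that many minutes also counts (off by default: the published
#' criterion is format-exact).
#'
#' @param result An `onset_extraction` from [extract_onsets()] (or any list
#'   with `note_id`, `outputs`, `n_outputs`).
#' @param gold A one-row tibble (or list) with `note_id` and `gold_onset`.
#' @param tolerance_min Match tolerance in minutes (default 0, exact).
#' @return List with `matched` (0 or 1) and `n_outputs`.
#' @examples
#' note <- clinical_note("n1", "HP", "01/01/2000 08:35", "cp 1 day ago")
#' res <- extract_onsets(note)
#' match_note(res, list(note_id = "n1", gold_onset = make_dt(1999, 12, 31, 8, 35)))
#' @export
match_note <- function(result, gold, tolerance_min = 0) {
  if (!identical(as.character(result$note_id), as.character(gold$note_id))) {
    abort_onsetdt(
      sprintf(
        "result note_id '%s' does not pair with gold note_id '%s'",
        result$note_id, gold$note_id
      ),
      "onsetdt_pairing_error"
    )
  }
  outs <- result$outputs
  matched <- 0L
  if (nrow(outs) > 0) {
    if (tolerance_min > 0) {
      matched <- as.integer(any(
        abs(as.numeric(outs$onset) - as.numeric(gold$gold_onset)) <=
          tolerance_min * 60
      ))
    } else {
      matched <- as.integer(any(outs$formatted == format_datetime(gold$gold_onset)))
    }
  }
  list(matched = matched, n_outputs = result$n_outputs)
}

#' Tabulate extraction results against gold annotations
#'
#' Builds a match report: a per-note table, a count grid keyed by
#' (note type, matched, number of outputs), and optionally a format-category
#' table with example strings for a set of detected expressions.
#'
#' @param results List of `onset_extraction` objects.
#' @param golds Tibble from [read_annotations_table()] (columns `note_id`,
#'   `gold_onset`); every result must have a gold row.
#' @param notes Optional notes tibble supplying `note_type` per note_id.
#' @param expressions Optional time-expression tibble (e.g. pooled output of
#'   [extract_expressions_regex()]) for the format table.
#' @param tolerance_min Passed to [match_note()].
#' @return An `onset_match_report` list with `per_note`, `grid`,
#'   `format_table`, `totals`.
#' @export
tabulate_matches <- function(results, golds, notes = NULL,
                             expressions = NULL, tolerance_min = 0) {
  ids <- map_chr(results, function(r) as.character(r$note_id))
  missing <- setdiff(ids, golds$note_id)
  if (length(missing) > 0) {
    abort_onsetdt(
      paste(
        "no gold annotation for note_id(s):",
        paste(missing, collapse = ", ")
      ),
      "onsetdt_pairing_error"
    )
  }
  per_note <- list_rbind(map(results, function(r) {
    g <- golds[golds$note_id == as.character(r$note_id), ]
    m <- match_note(r, g, tolerance_min = tolerance_min)
    tibble(
      note_id = as.character(r$note_id),
      matched = m$matched, n_outputs = m$n_outputs
    )
  }))
  if (!is.null(notes)) {
    per_note <- left_join(per_note, notes[c("note_id", "note_type")],
      by = "note_id"
    )
  } else {
    per_note$note_type <- NA_character_
  }
  per_note <- arrange(per_note, .data$note_id)
  grid <- count(per_note, .data$note_type, .data$matched, .data$n_outputs,
    name = "n_notes"
  )
  format_table <- NULL
  if (!is.null(expressions) && nrow(expressions) > 0) {
    expressions$format_category <- categorize_format(expressions)
    format_table <- expressions |>
      group_by(.data$format_category) |>
      summarise(
        n = n(),
        examples = paste(utils::head(unique(.data$raw), 3), collapse = ", ")
      ) |>
      ungroup()
  }
  structure(
    list(
      per_note = per_note,
      grid = grid,
      format_table = format_table,
      totals = list(
        n_notes = nrow(per_note),
        n_matched = sum(per_note$matched),
        prop_matched = if (nrow(per_note) > 0) {
          mean(per_note$matched)
        } else {
          NA_real_
        },
        n_expressions = if (is.null(format_table)) NULL else sum(format_table$n)
      )
    ),
    class = "onset_match_report"
  )
}

#' @export
print.onset_match_report <- function(x, ...) {
  cat(sprintf(
    "<onset_match_report> %d notes, %d matched (%.1f%%)\n",
    x$totals$n_notes, x$totals$n_matched, 100 * x$totals$prop_matched
  ))
  print(x$grid)
  if (!is.null(x$format_table)) {
    cat(sprintf("%d expressions by format:\n", x$totals$n_expressions))
    print(x$format_table)
  }
  invisible(x)
}

#' Write a match report to disk
#'
#' Serializes an `onset_match_report` as JSON and/or as delimiter-separated
#' tables (the output-count grid and the format-category table).
#'
#' @param report An `onset_match_report`.
#' @param json_path,grid_csv,format_csv Output paths (each optional).
#' @return Invisibly, the report.
#' @export
write_match_report <- function(report, json_path = NULL, grid_csv = NULL,
                               format_csv = NULL) {
  if (!is.null(json_path)) {
    payload <- list(
      totals = report$totals,
      grid = report$grid,
      format_table = report$format_table,
      per_note = report$per_note
    )
    jsonlite::write_json(payload, json_path,
      auto_unbox = TRUE, digits = NA, null = "null", POSIXt = "ISO8601"
    )
  }
  if (!is.null(grid_csv)) {
    readr::write_csv(report$grid, grid_csv)
  }
  if (!is.null(format_csv) && !is.null(report$format_table)) {
    readr::write_csv(report$format_table, format_csv)
  }
  invisible(report)
}
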