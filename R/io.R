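# Readers/writers and the programmatic surface behind the command-line
# script: delimiter-separated note/annotation tables in, JSON-per-note
# extraction records out. Output payloads carry no timestamps or run
# metadata, so identical inputs produce identical files.

guess_delim <- function(path) {
  if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a clinical notes table
#'
#' @param path Delimiter-separated file (delimiter guessed from the
#'   extension unless given) with columns `note_id`, `note_type`,
#'   `note_datetime`, `text`.
#' @param dialect Date-time dialect of the `note_datetime` column:
#'   `"canonical"` (`MM/DD/YYYY HH:MM`) or `"iso"` (`YYYY-MM-DD HH:MM`).
#' @param col_map Optional named character vector mapping the required names
#'   to the file's actual headers, e.g.
#'   `c(note_id = "NoteID", text = "NOTE_TEXT")`.
#' @param delim Field delimiter override.
#' @return Tibble of notes (one [clinical_note()] row each).
#' @export
read_notes_table <- function(path, dialect = c("canonical", "iso"),
                             col_map = NULL, delim = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_onsetdt(paste("notes file not found:", path), "onsetdt_io_error")
  }
  delim <- delim %||% guess_delim(path)
  raw <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[std]]] <- std
      }
    }
  }
  required <- c("note_id", "note_type", "note_datetime", "text")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_onsetdt(
      paste("notes table missing column(s):", paste(missing, collapse = ", ")),
      "onsetdt_schema_error"
    )
  }
  if (nrow(raw) == 0) {
    return(clinical_note("x", "HP", make_dt(2000, 1, 1), "")[0, ])
  }
  rows <- map(seq_len(nrow(raw)), function(i) {
    dt <- tryCatch(
      {
        if (dialect == "canonical") {
          parse_datetime(raw$note_datetime[i], strict = FALSE)
        } else {
          out <- as.POSIXct(raw$note_datetime[i],
            tz = DT_TZ,
            tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M")
          )
          if (is.na(out)) stop("unparseable")
          out
        }
      },
      error = function(e) {
        abort_onsetdt(
          sprintf(
            "row %d: cannot parse note_datetime '%s' (%s dialect)",
            i, raw$note_datetime[i], dialect
          ),
          "onsetdt_parse_error"
        )
      }
    )
    clinical_note(raw$note_id[i], raw$note_type[i], dt, raw$text[i])
  })
  list_rbind(rows)
}

#' Write a clinical notes table
#'
#' Inverse of [read_notes_table()] (canonical date-time dialect).
#'
#' @param notes Notes tibble.
#' @param path Output path (`.tsv` for tab-separated, else comma).
#' @return Invisibly, `path`.
#' @export
write_notes_table <- function(notes, path) {
  out <- tibble(
    note_id = notes$note_id,
    note_type = notes$note_type,
    note_datetime = format_datetime(notes$note_datetime),
    text = notes$text
  )
  readr::write_delim(out, path, delim = guess_delim(path))
  invisible(path)
}

#' Write gold annotations
#'
#' @param annotations Tibble with `note_id`, `gold_onset` (POSIXct).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_annotations_table <- function(annotations, path) {
  out <- tibble(
    note_id = annotations$note_id,
    gold_onset = format_datetime(annotations$gold_onset)
  )
  readr::write_csv(out, path)
  invisible(path)
}

result_record <- function(note, pipeline, mode) {
  if (pipeline == "hybrid") {
    res <- extract_onsets(note, mode = mode)
    outputs <- res$outputs
    rec <- list(
      note_id = note$note_id, pipeline = pipeline, mode = mode,
      n_outputs = res$n_outputs,
      outputs = outputs[c("start", "end", "raw", "stage", "formatted")],
      resolved = res$resolved_formatted
    )
  } else {
    exprs <- extract_expressions_regex(note$text)
    outputs <- anchor_regex_outputs(exprs, note$note_datetime,
      mode = mode, text = note$text
    )
    rec <- list(
      note_id = note$note_id, pipeline = pipeline, mode = mode,
      n_expressions = nrow(exprs),
      expressions = exprs[c("start", "end", "raw", "format_category")],
      n_outputs = nrow(outputs),
      outputs = outputs[c("start", "end", "raw", "stage", "formatted")]
    )
  }
  rec
}

#' Run an extraction pipeline over a notes file
#'
#' Reads a notes table, applies the chosen pipeline/mode to every note, and
#' writes one JSON object per note (JSON-lines) to `out_path`.
#'
#' @param notes_path Input notes table (see [read_notes_table()]).
#' @param pipeline `"hybrid"` or `"regex"`.
#' @param mode `"faithful"` or `"extended"`.
#' @param out_path Output JSON-lines path (`NULL` to skip writing).
#' @param dialect,col_map,delim Passed to [read_notes_table()].
#' @return Summary list: `n_notes`, `n_outputs_total`,
#'   `n_notes_with_output`, and the per-note records.
#' @export
run_extract <- function(notes_path, pipeline = c("hybrid", "regex"),
                        mode = c("faithful", "extended"), out_path = NULL,
                        dialect = "canonical", col_map = NULL, delim = NULL) {
  pipeline <- match.arg(pipeline)
  mode <- match.arg(mode)
  notes <- read_notes_table(notes_path,
    dialect = dialect, col_map = col_map,
    delim = delim
  )
  records <- map(seq_len(nrow(notes)), function(i) {
    result_record(notes[i, ], pipeline, mode)
  })
  if (!is.null(out_path)) {
    lines <- map_chr(records, function(r) {
      as.character(jsonlite::toJSON(r,
        auto_unbox = TRUE, digits = NA,
        dataframe = "rows", null = "null"
      ))
    })
    writeLines(lines, out_path)
  }
  n_out <- map_int(records, function(r) as.integer(r$n_outputs))
  list(
    n_notes = nrow(notes),
    n_outputs_total = sum(n_out),
    n_notes_with_output = sum(n_out > 0),
    records = records
  )
}

#' The worked example sentences shipped with the package
#'
#' A small fixture of short clinical sentences (with note timestamps)
#' exercising the documented behaviors of both pipelines: a compound
#' "last night at 9 pm" phrase with distractor numerics, a dotted-time
#' fallback case, a triage sentence with a wake-phrase elaboration of an
#' explicit time, and a military time + relative word combination.
#'
#' @return Notes tibble (see [read_notes_table()]).
#' @examples
#' example_sentences()$note_id
#' @export
example_sentences <- function() {
  read_notes_table(system.file("extdata", "example_sentences.csv",
    package = "onsetdt", mustWork = TRUE
  ))
}
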