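# File interchange: JSONL corpus, CSV registry tables (ISO-8601 dates),
# YAML generator configuration, and atomic report writing.

#' Write a sentence corpus as JSONL
#'
#' One JSON object per line with fields `patient_id`, `timestamp`, `text`
#' and (when present) `label`.
#'
#' @param corpus corpus data frame.
#' @param path output file.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  cols <- intersect(c("patient_id", "timestamp", "text", "label"),
                    names(corpus))
  df <- corpus[, cols, drop = FALSE]
  if ("timestamp" %in% cols) df$timestamp <- format(as.Date(df$timestamp))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(df)))
    writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                auto_unbox = TRUE), con)
  invisible(path)
}

#' Read a JSONL sentence corpus
#'
#' @param path JSONL file written by [write_corpus_jsonl()] or compatible.
#' @return corpus data frame with `timestamp` parsed as Date.
#' @export
read_corpus_jsonl <- function(path) {
  rows <- lapply(readLines(path, warn = FALSE), function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  if ("timestamp" %in% names(df)) df$timestamp <- as.Date(df$timestamp)
  df
}

#' Write the registry tables of a cohort as CSV files
#'
#' Writes `patients.csv`, `surgeries.csv`, `diagnosis_events.csv`,
#' `care_events.csv` and `status_notes.csv` with ISO-8601 dates.
#'
#' @param cohort a `smoking_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_registry_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "surgeries", "diagnosis_events", "care_events",
               "status_notes")) {
    df <- cohort[[nm]]
    for (col in names(df))
      if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]])
    .write_csv_atomic(df, file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Read registry tables written by [write_registry_csv()]
#'
#' @param dir directory holding the five CSV tables.
#' @return list shaped like a `smoking_cohort` (without a config).
#' @export
read_registry_csv <- function(dir) {
  out <- lapply(stats::setNames(nm = c("patients", "surgeries",
                                       "diagnosis_events", "care_events",
                                       "status_notes")), function(nm) {
    df <- utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                          stringsAsFactors = FALSE)
    for (col in intersect(c("date", "birth_date", "timestamp"), names(df)))
      df[[col]] <- as.Date(df[[col]])
    df
  })
  class(out) <- "smoking_cohort"
  out
}

.write_csv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write the report tables of a study to CSV
#'
#' Each table is written atomically (temporary file + rename) so a crashed
#' run never leaves a half-written report.
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(flow = report$flow, baseline = report$baseline,
                 yearly_status_ratios = report$yearly,
                 odds_ratios = report$or_table,
                 importance = report$importance)
  for (nm in names(tables))
    .write_csv_atomic(tables[[nm]], file.path(dir, paste0(nm, ".csv")))
  invisible(dir)
}

#' Build generator configurations from one YAML file
#'
#' The YAML file may hold a `corpus:` section and a `cohort:` section whose
#' keys are the arguments of [corpus_config()] and [cohort_config()]; a
#' top-level `seed:` applies to both unless overridden inside a section.
#'
#' @param path YAML file.
#' @return list with `corpus` ([corpus_config()]) and `cohort`
#'   ([cohort_config()]).
#' @export
generator_configs_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  corp <- y$corpus %||% list()
  coh <- y$cohort %||% list()
  if (is.null(corp$seed)) corp$seed <- seed
  if (is.null(coh$seed)) coh$seed <- seed
  if (!is.null(corp$class_mix)) corp$class_mix <- unlist(corp$class_mix)
  if (!is.null(coh$status_mix)) coh$status_mix <- unlist(coh$status_mix)
  list(corpus = do.call(corpus_config, corp),
       cohort = do.call(cohort_config, coh))
}
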