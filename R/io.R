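validate_date_col <- function(x) {
  parsed <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
  bad <- is.na(parsed) | format(parsed, "%Y-%m-%d") != x
  list(parsed = parsed, bad = bad | is.na(x))
}

#' Read a structured clinical event file
#'
#' Tab-separated with header; required columns `patient_id`, `event_date`
#' (ISO-8601), `code`; optional `source`, `attribute`, `cert_line`.
#' Malformed rows (bad dates, malformed codes) are collected into a rejects
#' tibble attached as the `rejects` attribute, never silently dropped.
#'
#' @param path File path.
#' @return A tibble of events with attribute `rejects`.
#' @export
read_events <- function(path) {
  df <- read_tsv_strict(path, c("patient_id", "event_date", "code"))
  dt <- validate_date_col(df$event_date)
  df$code <- normalise_code(df$code)
  bad_code <- !is_valid_read_code(df$code)
  bad <- dt$bad | bad_code
  rejects <- tibble::tibble(
    line = which(bad) + 1L,
    reason = ifelse(dt$bad[bad], "invalid event_date", "malformed code")
  )
  out <- df[!bad, ]
  out$event_date <- dt$parsed[!bad]
  if (!"source" %in% names(out)) out$source <- "structured"
  if (!"cert_line" %in% names(out)) out$cert_line <- NA_character_
  out <- tibble::as_tibble(out)
  attr(out, "rejects") <- rejects
  out
}

#' Read a free-text note file
#'
#' Tab-separated with header; required columns `patient_id`, `note_date`
#' (ISO-8601), `text` (tab characters escaped as `\\t`). Malformed rows go
#' to the `rejects` attribute.
#'
#' @param path File path.
#' @return A tibble of notes with attribute `rejects`.
#' @export
read_notes <- function(path) {
  df <- read_tsv_strict(path, c("patient_id", "note_date", "text"))
  dt <- validate_date_col(df$note_date)
  rejects <- tibble::tibble(line = which(dt$bad) + 1L, reason = "invalid note_date")
  out <- df[!dt$bad, ]
  out$note_date <- dt$parsed[!dt$bad]
  out$text <- stringr::str_replace_all(dplyr::coalesce(out$text, ""),
                                       stringr::fixed("\\t"), " ")
  out <- tibble::as_tibble(out)
  attr(out, "rejects") <- rejects
  out
}

#' Write a table as TSV
#'
#' Tab-separated output with header; dates in ISO-8601; free-text columns
#' are not expected (the pipeline emits coded data only). Reading the file
#' back with [read_events()] / [read_notes()] / `readr::read_tsv()` yields
#' the same records.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_report <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(~ inherits(.x, "Date")),
                                      ~ format(.x, "%Y-%m-%d")))
  drop <- vapply(x, is.list, logical(1))
  readr::write_tsv(x[, !drop, drop = FALSE], path, progress = FALSE)
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' @param cohort A list of tibbles (e.g. from [generate_mi_cohort()] or
#'   [generate_death_cohort()]).
#' @param dir Output directory, created if needed.
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(cohort)) {
    write_report(cohort[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}
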