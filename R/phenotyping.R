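#' Convert engine output to clinical events
#'
#' Reshapes a coded-output tibble (see [link_notes()]) into the clinical
#' event form used by the phenotyping and cause-of-death analyses, tagged
#' with source "freetext". Structured events default to attribute
#' `current_or_previous`.
#'
#' @param outputs Coded-output tibble.
#' @return Tibble with columns `patient_id`, `event_date`, `code`, `source`,
#'   `attribute`, `cert_line`, `note_idx`, `record_order`.
#' @export
outputs_as_events <- function(outputs) {
  tibble::tibble(
    patient_id = outputs$patient_id,
    event_date = outputs$event_date,
    code = outputs$code,
    source = "freetext",
    attribute = outputs$attribute,
    cert_line = if ("cert_line" %in% names(outputs)) outputs$cert_line else NA_character_,
    note_idx = if ("note_idx" %in% names(outputs)) outputs$note_idx else NA_integer_,
    record_order = seq_len(nrow(outputs))
  )
}

# Normalise a structured event table to the combined event schema.
events_as_combined <- function(events) {
  tibble::tibble(
    patient_id = events$patient_id,
    event_date = as.Date(events$event_date),
    code = events$code,
    source = if ("source" %in% names(events)) events$source else "structured",
    attribute = if ("attribute" %in% names(events)) events$attribute else "current_or_previous",
    cert_line = if ("cert_line" %in% names(events)) events$cert_line else NA_character_,
    note_idx = NA_integer_,
    record_order = seq_len(nrow(events))
  )
}

#' Combine structured events and coded free-text output
#'
#' @param events Structured event tibble (patient_id, event_date, code,
#'   optional source/attribute/cert_line columns).
#' @param outputs Engine output tibble, or NULL.
#' @return A combined event tibble.
#' @export
combine_events <- function(events, outputs = NULL) {
  combined <- events_as_combined(events)
  if (!is.null(outputs) && nrow(outputs) > 0) {
    combined <- dplyr::bind_rows(combined, outputs_as_events(outputs))
  }
  combined
}

#' Classify the subtype of a myocardial infarction
#'
#' For each registry case, considers STEMI/NSTEMI-bearing records dated
#' between the MI date and `window_days` after it. Structured records take
#' precedence over free-text records (free text is used only when no
#' structured subtype record exists in the window); within a source the
#' record closest to the MI date wins, with ties resolved by record entry
#' order. Records with attribute `absent` or `suspected` are ignored;
#' generic (non-subtype) MI codes never produce a call.
#'
#' @param events Combined event tibble (see [combine_events()]).
#' @param cases Tibble with `patient_id`, `mi_date`.
#' @param window_days Classification window after the MI date, default 30.
#' @param config An [engine_config()] (supplies the subtype code sets).
#' @return A tibble with one row per case: `patient_id`, `call` (STEMI,
#'   NSTEMI, unclassified), `source_used` (structured, freetext, none),
#'   `record_date`.
#' @export
classify_mi_subtype <- function(events, cases, window_days = 30L,
                                config = engine_config()) {
  stopifnot(all(c("patient_id", "mi_date") %in% names(cases)))
  cases$mi_date <- as.Date(cases$mi_date)
  sub <- events %>%
    dplyr::filter(.data$code %in% c(config$stemi_codes, config$nstemi_codes),
                  !.data$attribute %in% c("absent", "suspected")) %>%
    dplyr::inner_join(cases[, c("patient_id", "mi_date")], by = "patient_id") %>%
    dplyr::filter(.data$event_date >= .data$mi_date,
                  .data$event_date <= .data$mi_date + window_days) %>%
    dplyr::mutate(
      subtype = ifelse(.data$code %in% config$stemi_codes, "STEMI", "NSTEMI"),
      src_rank = ifelse(.data$source == "structured", 1L, 2L),
      dist = as.integer(.data$event_date - .data$mi_date)
    ) %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::arrange(.data$src_rank, .data$dist, .data$record_order, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup()

  cases %>%
    dplyr::left_join(sub[, c("patient_id", "subtype", "source", "event_date")],
                     by = "patient_id") %>%
    dplyr::transmute(
      patient_id = .data$patient_id,
      call = dplyr::coalesce(.data$subtype, "unclassified"),
      source_used = dplyr::coalesce(.data$source, "none"),
      record_date = .data$event_date
    )
}

#' Cross-tabulate subtype calls against the registry gold standard
#'
#' @param calls Output of [classify_mi_subtype()].
#' @param cases Tibble with `patient_id`, `gold_subtype` (STEMI or NSTEMI).
#' @return A `subtype_confusion` object: a tibble of counts over gold x
#'   source x call with gold totals as attributes.
#' @export
tabulate_subtype_confusion <- function(calls, cases) {
  stopifnot(all(c("patient_id", "gold_subtype") %in% names(cases)))
  unknown <- setdiff(calls$patient_id, cases$patient_id)
  if (length(unknown) > 0) {
    stop("call(s) for unknown patient(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  grid <- tidyr::expand_grid(
    gold = c("STEMI", "NSTEMI"),
    source = c("structured", "freetext", "none"),
    call = c("STEMI", "NSTEMI", "unclassified")
  ) %>%
    dplyr::filter((.data$source == "none") == (.data$call == "unclassified"))
  counts <- cases %>%
    dplyr::inner_join(calls, by = "patient_id") %>%
    dplyr::count(gold = .data$gold_subtype, source = .data$source_used,
                 call = .data$call)
  out <- grid %>%
    dplyr::left_join(counts, by = c("gold", "source", "call")) %>%
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  gold_totals <- out %>% dplyr::count(.data$gold, wt = .data$n, name = "total")
  structure(out, class = c("subtype_confusion", class(out)),
            gold_totals = stats::setNames(gold_totals$total, gold_totals$gold))
}

#' @export
print.subtype_confusion <- function(x, ...) {
  tot <- attr(x, "gold_totals")
  cat("MI subtype confusion (gold totals: ",
      paste(names(tot), tot, sep = " = ", collapse = ", "), ")\n", sep = "")
  print(tibble::as_tibble(x), n = Inf)
  invisible(x)
}

confusion_cell <- function(confusion, gold, source, call) {
  sum(confusion$n[confusion$gold %in% gold & confusion$source %in% source &
                    confusion$call %in% call])
}

#' Sensitivity, specificity and PPV of subtype classification
#'
#' Computes per-class (STEMI, NSTEMI) sensitivity, specificity and positive
#' predictive value from a subtype confusion, either using structured calls
#' only (free-text calls count as unclassified) or using both sources.
#' Confidence intervals are Wilson score intervals; percentages are reported
#' to one decimal.
#'
#' @param confusion A `subtype_confusion` object.
#' @param mode "structured_only" or "structured_plus_freetext".
#' @param level Confidence level.
#' @param ci_method CI method, see [wilson_ci()].
#' @return A tibble with columns `class`, `mode`, `metric`, `k`, `n`,
#'   `point`, `ci_low`, `ci_high`, `pct` (point as a half-up-rounded
#'   percentage to 1 decimal) and `label`.
#' @export
subtype_metrics <- function(confusion,
                            mode = c("structured_only", "structured_plus_freetext"),
                            level = 0.95, ci_method = "wilson") {
  mode <- match.arg(mode)
  sources <- if (mode == "structured_only") "structured" else c("structured", "freetext")
  classes <- c("STEMI", "NSTEMI")
  purrr::map_dfr(classes, function(cl) {
    other <- setdiff(classes, cl)
    tp <- confusion_cell(confusion, cl, sources, cl)
    fp <- confusion_cell(confusion, other, sources, cl)
    gold_c <- confusion_cell(confusion, cl, c("structured", "freetext", "none"),
                             c("STEMI", "NSTEMI", "unclassified"))
    gold_o <- confusion_cell(confusion, other, c("structured", "freetext", "none"),
                             c("STEMI", "NSTEMI", "unclassified"))
    m <- binary_metrics(tp = tp, fp = fp, fn = gold_c - tp, tn = gold_o - fp,
                        level = level, method = ci_method)
    m$class <- cl
    m$mode <- mode
    m
  }) %>%
    dplyr::mutate(
      pct = round_half_up(100 * .data$point, 1),
      label = format_pct_ci(.data$point, .data$ci_low, .data$ci_high)
    ) %>%
    dplyr::select("class", "mode", "metric", "k", "n", "point", "ci_low",
                  "ci_high", "pct", "label")
}

#' Concordance of source-specific subtype calls with the registry
#'
#' Among registry cases classified by the given source, the fraction whose
#' call equals the registry gold subtype.
#'
#' @param confusion A `subtype_confusion` object.
#' @param source "structured" or "freetext".
#' @param level Confidence level.
#' @return A one-row tibble: `source`, `k`, `n`, `point`, `ci_low`,
#'   `ci_high`, `pct`, `label`; `point` is NA when the source classified no
#'   case.
#' @export
subtype_concordance <- function(confusion, source = c("structured", "freetext"),
                                level = 0.95) {
  source <- match.arg(source)
  n <- confusion_cell(confusion, c("STEMI", "NSTEMI"), source,
                      c("STEMI", "NSTEMI"))
  k <- confusion_cell(confusion, "STEMI", source, "STEMI") +
    confusion_cell(confusion, "NSTEMI", source, "NSTEMI")
  if (n == 0) {
    return(tibble::tibble(source = source, k = NA_integer_, n = 0L,
                          point = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, pct = NA_real_, label = "-"))
  }
  ci <- wilson_ci(k, n, level = level)
  tibble::tibble(source = source, k = k, n = n, point = ci$point,
                 ci_low = ci$ci_low, ci_high = ci$ci_high,
                 pct = round_half_up(100 * ci$point, 1),
                 label = format_pct_ci(ci$point, ci$ci_low, ci$ci_high))
}

#' Default symptom and investigation code sets
#'
#' The named code groups and counting windows (days relative to the MI date)
#' used by [symptom_recording_table()].
#'
#' @return A tibble with columns `item`, `codes` (list column), `from`, `to`.
#' @export
default_symptom_codesets <- function() {
  tibble::tibble(
    item = c("pulse_rate", "blood_pressure", "lv_function", "angiogram",
             "irregular_pulse", "atrial_fibrillation", "chest_pain_7d",
             "chest_pain_90d", "breathlessness_7d", "breathlessness_90d"),
    codes = list("242..00", "246..00", "G581.13", "3887.00", "2432.00",
                 "G573.00", c("182..00", "R065.00"), c("182..00", "R065.00"),
                 "173..00", "173..00"),
    from = c(rep(-90L, 6), -7L, -90L, -7L, -90L),
    to = c(rep(90L, 6), 0L, 0L, 0L, 0L)
  )
}

#' Symptom and investigation recording by source
#'
#' For each code-set item, counts the patients with at least one qualifying
#' record (attribute neither `absent` nor `suspected`) inside the item's
#' window around the MI date, using structured records only and using either
#' source, and reports the percent increase obtained by adding free text
#' (rounded half-up to the nearest integer; undefined when the structured
#' count is zero).
#'
#' @param events Combined event tibble (see [combine_events()]).
#' @param cases Tibble with `patient_id`, `mi_date` for the whole cohort.
#' @param codesets See [default_symptom_codesets()].
#' @return A tibble with columns `item`, `n_structured`, `n_either`,
#'   `pct_structured`, `pct_either`, `pct_increase`.
#' @export
symptom_recording_table <- function(events, cases,
                                    codesets = default_symptom_codesets()) {
  cases$mi_date <- as.Date(cases$mi_date)
  n_pat <- nrow(cases)
  ev <- events %>%
    dplyr::filter(!.data$attribute %in% c("absent", "suspected")) %>%
    dplyr::inner_join(cases[, c("patient_id", "mi_date")], by = "patient_id") %>%
    dplyr::mutate(offset = as.integer(.data$event_date - .data$mi_date))
  purrr::map_dfr(seq_len(nrow(codesets)), function(i) {
    sel <- ev %>%
      dplyr::filter(.data$code %in% codesets$codes[[i]],
                    .data$offset >= codesets$from[i],
                    .data$offset <= codesets$to[i])
    n_s <- dplyr::n_distinct(sel$patient_id[sel$source == "structured"])
    n_e <- dplyr::n_distinct(sel$patient_id)
    tibble::tibble(
      item = codesets$item[i],
      n_structured = n_s, n_either = n_e,
      pct_structured = round_half_up(100 * n_s / n_pat, 1),
      pct_either = round_half_up(100 * n_e / n_pat, 1),
      pct_increase = if (n_s > 0) round_half_up(100 * (n_e / n_s - 1), 0) else NA_real_
    )
  })
}

#' Run the full MI phenotyping analysis on a cohort
#'
#' Codes the cohort's notes with the engine, combines them with the
#' structured events, classifies the registry cases' MI subtype, tabulates
#' the confusion and computes the symptom recording table.
#'
#' @param cohort Output of [generate_mi_cohort()] (or a list with the same
#'   elements read from files).
#' @param resources A `notecoder_resources` list.
#' @param window_days Subtype classification window, default 30.
#' @return A list with `coded` (engine output), `confusion`, `metrics` (all
#'   modes bound), `concordance`, and `symptoms`.
#' @export
analyse_mi_cohort <- function(cohort, resources = default_resources(),
                              window_days = 30L) {
  coded <- link_notes(cohort$notes, resources)
  stopifnot(verify_coded_only(coded, resources)$pass)
  combined <- combine_events(cohort$events, coded)
  calls <- classify_mi_subtype(combined, cohort$gold, window_days = window_days,
                               config = resources$config)
  confusion <- tabulate_subtype_confusion(calls, cohort$gold)
  metrics <- dplyr::bind_rows(
    subtype_metrics(confusion, "structured_only"),
    subtype_metrics(confusion, "structured_plus_freetext")
  )
  concordance <- dplyr::bind_rows(
    subtype_concordance(confusion, "structured"),
    subtype_concordance(confusion, "freetext")
  )
  symptoms <- symptom_recording_table(combined, cohort$mi_dates)
  list(coded = coded, confusion = confusion, metrics = metrics,
       concordance = concordance, symptoms = symptoms)
}
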