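cert_line_order <- c("1a" = 1L, "1b" = 2L, "1c" = 3L, "2" = 4L)
category_priority <- c(transcribed_certificate = 1L, explicit_statement = 2L,
                       implied_diagnosis = 3L)

#' Categorise post-death cause-of-death evidence
#'
#' Groups a patient's records dated on or after death into cause candidates:
#' records carrying a certificate line marker (1a/1b/1c/ii in free text, the
#' certificate-line field of structured records) become a
#' `transcribed_certificate` candidate with ordered lines; diagnosis records
#' accompanied by a same-source, same-date cause-of-death marker become an
#' `explicit_statement` candidate; any other diagnosis record becomes part of
#' an `implied_diagnosis` candidate. One candidate is built per category and
#' source.
#'
#' @param events Combined event tibble (see [combine_events()]) for one
#'   patient, restricted by this function to records dated on/after
#'   `death_date`.
#' @param death_date The patient's date of death.
#' @param resources A `notecoder_resources` list.
#' @return A tibble of candidates: `category`, `source`, `record_date`, and
#'   `lines` (list column of tibbles with `cert_line`, `code` - certificate
#'   lines, or marker-free code lists for the other categories).
#' @export
categorize_cause_records <- function(events, death_date, resources) {
  death_date <- as.Date(death_date)
  ev <- events %>%
    dplyr::filter(.data$event_date >= death_date) %>%
    dplyr::arrange(.data$event_date, .data$record_order)
  empty <- tibble::tibble(category = character(0), source = character(0),
                          record_date = as.Date(character(0)), lines = list())
  if (nrow(ev) == 0) return(empty)

  marker_code <- resources$config$cause_marker_code
  known <- ev$code %in% resources$terminology$code
  ev$is_dx <- FALSE
  ev$is_dx[known] <- is_diagnosis_code(ev$code[known])

  out <- list()
  cert <- ev[!is.na(ev$cert_line), ]
  if (nrow(cert) > 0) {
    out[[length(out) + 1]] <- cert %>%
      dplyr::group_by(.data$source) %>%
      dplyr::arrange(cert_line_order[.data$cert_line], .data$record_order,
                     .by_group = TRUE) %>%
      dplyr::summarise(
        category = "transcribed_certificate",
        record_date = min(.data$event_date),
        lines = list(tibble::tibble(cert_line = cert_line, code = code)),
        .groups = "drop"
      )
  }
  rest <- ev[is.na(ev$cert_line), ]
  markers <- rest[rest$code == marker_code, ]
  dx <- rest[rest$is_dx, ]
  if (nrow(dx) > 0) {
    key <- paste(dx$source, dx$event_date)
    mkey <- paste(markers$source, markers$event_date)
    explicit <- dx[key %in% mkey, ]
    implied <- dx[!key %in% mkey, ]
    for (d in list(list(df = explicit, cat = "explicit_statement"),
                   list(df = implied, cat = "implied_diagnosis"))) {
      if (nrow(d$df) > 0) {
        out[[length(out) + 1]] <- d$df %>%
          dplyr::group_by(.data$source) %>%
          dplyr::summarise(
            category = d$cat,
            record_date = min(.data$event_date),
            lines = list(tibble::tibble(cert_line = NA_character_, code = code)),
            .groups = "drop"
          )
      }
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)[, c("category", "source", "record_date", "lines")]
}

#' Select the primary cause-of-death candidate
#'
#' Priority is by specificity of the recording category: transcribed
#' certificate > explicit statement > implied diagnosis, regardless of
#' source; within a category, structured records come before free text;
#' within that, the earliest record. Deterministic: any nonempty candidate
#' list yields exactly one selection.
#'
#' @param candidates Output of [categorize_cause_records()].
#' @return A one-row tibble, or NULL for an empty candidate list.
#' @export
select_primary_candidate <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  candidates %>%
    dplyr::arrange(category_priority[.data$category],
                   ifelse(.data$source == "structured", 1L, 2L),
                   .data$record_date) %>%
    dplyr::slice(1)
}

# "could c give rise to u": any causal-sequence row whose cause prefix
# matches c and consequence prefix matches u.
could_give_rise <- function(cause_icd, consequence_icd, causal) {
  if (is.null(causal) || nrow(causal) == 0) return(FALSE)
  any(startsWith(cause_icd, causal$cause_icd10_prefix) &
        startsWith(consequence_icd, causal$consequence_icd10_prefix))
}

#' Select the underlying cause of death from a candidate
#'
#' For a transcribed certificate: the condition on the lowest used line of
#' Part 1 is the underlying cause if, per the causal-sequence table, it
#' could give rise to every condition entered above it (the General
#' Principle); otherwise the first-mentioned Part-1 condition (line 1a) is
#' selected (simplified selection rule). Part-2 codes are never selected.
#' For explicit statements and implied diagnoses: the first code in record
#' order, with ill-defined codes (R00-R99) deprioritised below any
#' non-R code.
#'
#' @param candidate A one-row candidate (see [select_primary_candidate()]).
#' @param resources A `notecoder_resources` list (supplies the Read to
#'   ICD-10 map and the causal-sequence table).
#' @return A single ICD-10 code.
#' @export
select_underlying_cause <- function(candidate, resources) {
  if (is.null(candidate) || nrow(candidate) == 0) stop("empty candidate")
  lines <- candidate$lines[[1]]
  if (nrow(lines) == 0) stop("empty certificate")
  lines$icd10 <- map_read_to_icd10(lines$code, resources)

  if (candidate$category == "transcribed_certificate") {
    part1 <- lines[lines$cert_line %in% c("1a", "1b", "1c"), ]
    if (nrow(part1) == 0) stop("empty certificate")
    part1 <- part1[order(cert_line_order[part1$cert_line]), ]
    lowest <- nrow(part1)
    if (lowest == 1) return(part1$icd10[1])
    above <- part1$icd10[seq_len(lowest - 1)]
    ok <- all(vapply(above, function(u) {
      could_give_rise(part1$icd10[lowest], u, resources$causal)
    }, logical(1)))
    if (ok) part1$icd10[lowest] else part1$icd10[1]
  } else {
    r_code <- startsWith(lines$icd10, "R")
    ordered <- lines$icd10[order(r_code)]
    ordered[1]
  }
}

#' Compare a primary-care cause with the registry cause
#'
#' @param pc Primary-care underlying ICD-10 code, or NA.
#' @param registry Registry underlying ICD-10 code.
#' @param match_chars Characters of the category compared at the middle
#'   match level (3 by default; 2 for a literal two-character prefix).
#' @return One of "exact_code", "category_3char", "same_chapter",
#'   "different", "no_pc_cause". Vectorised over `pc`/`registry`.
#' @examples
#' compare_cause("I500", "I501")
#' @export
compare_cause <- function(pc, registry, match_chars = 3L) {
  n <- max(length(pc), length(registry))
  pc <- rep_len(pc, n); registry <- rep_len(registry, n)
  if (any(is.na(registry))) stop("registry code must be present")
  bad <- !is_valid_icd10(registry) | (!is.na(pc) & !is_valid_icd10(pc))
  if (any(bad)) stop("malformed ICD-10 code(s)")
  out <- rep("no_pc_cause", n)
  has <- !is.na(pc)
  reg_ch <- icd10_chapter(registry)
  if (any(has)) {
    pc_ch <- rep(NA_character_, n)
    pc_ch[has] <- icd10_chapter(pc[has])
    out[has] <- dplyr::case_when(
      pc[has] == registry[has] ~ "exact_code",
      substr(pc[has], 1, match_chars) == substr(registry[has], 1, match_chars) ~ "category_3char",
      pc_ch[has] == reg_ch[has] ~ "same_chapter",
      TRUE ~ "different"
    )
  }
  out
}

#' Extract the primary-care underlying cause for a death cohort
#'
#' Runs the engine over the cohort's post-death notes, combines them with
#' the structured events, categorises the evidence per patient, selects the
#' primary candidate and the underlying cause, and compares it with the
#' registry gold standard.
#'
#' @param cohort Output of [generate_death_cohort()] (or a list with
#'   elements `events`, `notes`, `registry` read from files).
#' @param resources A `notecoder_resources` list.
#' @param match_chars See [compare_cause()].
#' @return A tibble of death cases: `patient_id`, `death_date`,
#'   `registry_underlying`, `pc_underlying`, `category`, `source`,
#'   `match_level`.
#' @export
analyse_deaths <- function(cohort, resources = default_resources(),
                           match_chars = resources$config$icd10_match_chars) {
  coded <- link_notes(cohort$notes, resources)
  stopifnot(verify_coded_only(coded, resources)$pass)
  combined <- combine_events(cohort$events, coded)
  reg <- cohort$registry
  reg$death_date <- as.Date(reg$death_date)

  split_ev <- split(combined, combined$patient_id)
  res <- purrr::map_dfr(seq_len(nrow(reg)), function(i) {
    pid <- reg$patient_id[i]
    ev <- split_ev[[pid]]
    cand <- if (is.null(ev)) NULL else
      categorize_cause_records(ev, reg$death_date[i], resources)
    sel <- select_primary_candidate(cand)
    if (is.null(sel)) {
      tibble::tibble(patient_id = pid, pc_underlying = NA_character_,
                     category = "none", source = "none")
    } else {
      tibble::tibble(patient_id = pid,
                     pc_underlying = select_underlying_cause(sel, resources),
                     category = sel$category,
                     source = ifelse(sel$source == "structured", "coded", "freetext"))
    }
  })
  reg %>%
    dplyr::left_join(res, by = "patient_id") %>%
    dplyr::mutate(match_level = compare_cause(.data$pc_underlying,
                                              .data$registry_underlying,
                                              match_chars = match_chars))
}

#' Cause-of-death concordance report
#'
#' Summarises a death-case table into (a) counts of deaths per recording
#' category, source and period, including deaths with no primary-care cause,
#' with the per-category exact-match accuracy; (b) cumulative match-level
#' proportions (exact code, same category, same chapter) by source and
#' pooled; and (c) sensitivity and specificity for the coronary,
#' cerebrovascular and cancer cause groups by source. All intervals are
#' Wilson score intervals; percentages are reported to one decimal.
#'
#' @param cases Output of [analyse_deaths()].
#' @param period_breaks Start years of the reporting bands plus the end
#'   year (passed to [cut()]); default 3-year bands 2001-2009.
#' @param level Confidence level.
#' @return An object of class `death_concordance`: a list with tibbles
#'   `recording`, `matching`, `groups` and `pooled`.
#' @export
concordance_report <- function(cases, period_breaks = c(2001, 2004, 2007, 2010),
                               level = 0.95) {
  cases <- cases %>%
    dplyr::mutate(
      year = as.integer(format(as.Date(.data$death_date), "%Y")),
      period = cut(.data$year, breaks = period_breaks, right = FALSE,
                   labels = paste(utils::head(period_breaks, -1),
                                  utils::tail(period_breaks, -1) - 1, sep = "-"))
    )

  recording <- cases %>%
    dplyr::count(.data$category, .data$source, .data$period) %>%
    tidyr::pivot_wider(names_from = "period", values_from = "n",
                       values_fill = 0L) %>%
    dplyr::left_join(
      cases %>%
        dplyr::filter(.data$category != "none") %>%
        dplyr::group_by(.data$category, .data$source) %>%
        dplyr::summarise(
          n_cat = dplyr::n(),
          n_exact = sum(.data$match_level == "exact_code"),
          .groups = "drop"
        ) %>%
        dplyr::mutate(accuracy = .data$n_exact / .data$n_cat,
                      accuracy_label = {
                        ci <- wilson_ci(.data$n_exact, .data$n_cat, level = level)
                        format_pct_ci(ci$point, ci$ci_low, ci$ci_high, digits = 0)
                      }),
      by = c("category", "source")
    )

  with_cause <- cases %>% dplyr::filter(!is.na(.data$pc_underlying))
  match_tab <- function(df, label) {
    n <- nrow(df)
    if (n == 0) {
      return(tibble::tibble(
        source = label,
        level = c("same_underlying_cause", "same_category", "same_chapter"),
        k = NA_integer_, n = 0L, point = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, pct = NA_real_))
    }
    lv <- df$match_level
    k_exact <- sum(lv == "exact_code")
    k_cat <- k_exact + sum(lv == "category_3char")
    k_chap <- k_cat + sum(lv == "same_chapter")
    purrr::map2_dfr(
      c("same_underlying_cause", "same_category", "same_chapter"),
      c(k_exact, k_cat, k_chap),
      function(what, k) {
        ci <- wilson_ci(k, n, level = level)
        tibble::tibble(source = label, level = what, k = k, n = n,
                       point = ci$point, ci_low = ci$ci_low,
                       ci_high = ci$ci_high,
                       pct = round_half_up(100 * ci$point, 1))
      }
    )
  }
  matching <- dplyr::bind_rows(
    match_tab(with_cause[with_cause$source == "freetext", ], "freetext"),
    match_tab(with_cause[with_cause$source == "coded", ], "coded"),
    match_tab(with_cause, "pooled")
  )

  groups <- purrr::map_dfr(c("coronary", "cerebrovascular", "cancer"), function(g) {
    purrr::map_dfr(c("freetext", "coded"), function(s) {
      df <- with_cause[with_cause$source == s, ]
      reg_in <- in_cause_group(df$registry_underlying, g)
      pc_in <- in_cause_group(df$pc_underlying, g)
      m <- binary_metrics(tp = sum(reg_in & pc_in), fp = sum(!reg_in & pc_in),
                          fn = sum(reg_in & !pc_in), tn = sum(!reg_in & !pc_in),
                          level = level)
      m %>%
        dplyr::filter(.data$metric %in% c("sensitivity", "specificity")) %>%
        dplyr::mutate(group = g, source = s,
                      pct = round_half_up(100 * .data$point, 1),
                      label = format_pct_ci(.data$point, .data$ci_low, .data$ci_high))
    })
  }) %>%
    dplyr::select("group", "source", "metric", "k", "n", "point", "ci_low",
                  "ci_high", "pct", "label")

  pooled <- matching %>% dplyr::filter(.data$source == "pooled")
  structure(list(recording = recording, matching = matching, groups = groups,
                 pooled = pooled, n_cases = nrow(cases),
                 n_with_cause = nrow(with_cause)),
            class = "death_concordance")
}

#' @export
print.death_concordance <- function(x, ...) {
  cat("Cause-of-death concordance:", x$n_with_cause, "of", x$n_cases,
      "deaths with a primary-care cause\n\n")
  cat("Match levels (cumulative):\n")
  print(x$matching, n = Inf)
  cat("\nCause groups:\n")
  print(x$groups, n = Inf)
  invisible(x)
}
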