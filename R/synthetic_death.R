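# Default per-source allocation of (registry underlying cause, primary-care
# underlying cause) pairs for the 1022 deaths with a cause recorded in
# primary care. Rows are grouped by registry cause group; the pair choice
# fixes the match level (exact / 3-character category / chapter / different)
# and the cause-group confusion, so that the pooled and per-source
# match-level counts and the per-group sensitivity/specificity of the
# default cohort equal the reported ones.
#' Default death-cohort cause-pair allocation
#'
#' @return A tibble with columns `source`, `gold_icd`, `pc_icd`, `n`.
#' @export
default_death_match_allocation <- function() {
  tibble::tribble(
    ~source,    ~gold_icd, ~pc_icd, ~n,
    # free text (381): 184 exact, 38 category, 56 chapter, 103 different
    "freetext", "I219", "I219", 15L,
    "freetext", "I251", "I251", 10L,
    "freetext", "I219", "I211",  4L,
    "freetext", "I219", "I251",  3L,
    "freetext", "I219", "I469",  5L,
    "freetext", "I211", "I500",  5L,
    "freetext", "I219", "J189",  7L,
    "freetext", "I639", "I639", 16L,
    "freetext", "I619", "I619",  8L,
    "freetext", "I639", "I630",  4L,
    "freetext", "I639", "I619",  4L,
    "freetext", "I639", "I500",  8L,
    "freetext", "I639", "F03X",  4L,
    "freetext", "I619", "J180",  4L,
    "freetext", "C509", "C509", 40L,
    "freetext", "C349", "C349", 25L,
    "freetext", "C61X", "C61X", 15L,
    "freetext", "C509", "C500",  8L,
    "freetext", "C509", "C349",  5L,
    "freetext", "C509", "D489",  3L,
    "freetext", "C349", "J189",  4L,
    "freetext", "J189", "J189", 20L,
    "freetext", "E149", "E149", 15L,
    "freetext", "F03X", "F03X", 10L,
    "freetext", "I509", "I509", 10L,
    "freetext", "J189", "J180", 22L,
    "freetext", "J189", "J449", 23L,
    "freetext", "R54X", "I219",  7L,
    "freetext", "R54X", "I639",  5L,
    "freetext", "R54X", "C509", 12L,
    "freetext", "N179", "J189", 30L,
    "freetext", "A419", "E149", 30L,
    # coded (641): 293 exact, 78 category, 92 chapter, 178 different
    "coded",    "I219", "I219", 40L,
    "coded",    "I251", "I251", 12L,
    "coded",    "I209", "I209",  8L,
    "coded",    "I219", "I211", 10L,
    "coded",    "I219", "I251",  8L,
    "coded",    "I219", "I469",  8L,
    "coded",    "I211", "I501",  8L,
    "coded",    "I219", "J189", 20L,
    "coded",    "I639", "I639", 12L,
    "coded",    "I619", "I619",  8L,
    "coded",    "I639", "I630",  6L,
    "coded",    "I639", "I619",  5L,
    "coded",    "I639", "I500", 10L,
    "coded",    "I639", "F03X",  6L,
    "coded",    "I619", "J180",  6L,
    "coded",    "C509", "C509", 50L,
    "coded",    "C349", "C349", 40L,
    "coded",    "C61X", "C61X", 20L,
    "coded",    "C509", "C500", 15L,
    "coded",    "C509", "C349", 10L,
    "coded",    "C509", "D489", 10L,
    "coded",    "C349", "J189", 23L,
    "coded",    "J189", "J189", 40L,
    "coded",    "E149", "E149", 25L,
    "coded",    "F03X", "F03X", 18L,
    "coded",    "I509", "I509", 20L,
    "coded",    "J189", "J180", 30L,
    "coded",    "I500", "I501", 17L,
    "coded",    "J189", "J449", 33L,
    "coded",    "R54X", "I219",  9L,
    "coded",    "R54X", "I619", 13L,
    "coded",    "R54X", "C509",  7L,
    "coded",    "N179", "J189", 50L,
    "coded",    "A419", "E149", 44L
  )
}

#' Default death-cohort recording-category allocation
#'
#' Counts of deaths per 3-year period by how the cause is recorded in
#' primary care: transcribed death certificate entry, explicit
#' cause-of-death statement, diagnosis dated on or after death, or no cause
#' recorded, each split by structured (coded) versus free-text source.
#'
#' @return A tibble with columns `period`, `category`, `source`, `n`.
#' @export
default_death_category_allocation <- function() {
  tibble::tribble(
    ~period, ~category,     ~source,    ~n,
    1L, "transcribed_certificate", "coded",     46L,
    1L, "transcribed_certificate", "freetext",  32L,
    1L, "explicit_statement",      "coded",     26L,
    1L, "explicit_statement",      "freetext",  16L,
    1L, "implied_diagnosis",       "coded",    140L,
    1L, "implied_diagnosis",       "freetext",  69L,
    1L, "none",                    "none",     271L,
    2L, "transcribed_certificate", "coded",    103L,
    2L, "transcribed_certificate", "freetext",  41L,
    2L, "explicit_statement",      "coded",     47L,
    2L, "explicit_statement",      "freetext",  17L,
    2L, "implied_diagnosis",       "coded",     79L,
    2L, "implied_diagnosis",       "freetext",  67L,
    2L, "none",                    "none",     246L,
    3L, "transcribed_certificate", "coded",    112L,
    3L, "transcribed_certificate", "freetext",  47L,
    3L, "explicit_statement",      "coded",     36L,
    3L, "explicit_statement",      "freetext",  16L,
    3L, "implied_diagnosis",       "coded",     52L,
    3L, "implied_diagnosis",       "freetext",  76L,
    3L, "none",                    "none",     261L
  )
}

# How many exact-match cases go to each recording category (per source);
# chosen proportional to the reported per-category accuracies subject to the
# per-source exact-match totals.
death_exact_by_category <- function() {
  tibble::tribble(
    ~source,    ~category,                 ~n_exact,
    "coded",    "transcribed_certificate", 148L,
    "coded",    "explicit_statement",       31L,
    "coded",    "implied_diagnosis",       114L,
    "freetext", "transcribed_certificate",  67L,
    "freetext", "explicit_statement",       28L,
    "freetext", "implied_diagnosis",        89L
  )
}

#' Specification for a synthetic death cohort
#'
#' @param match_allocation See [default_death_match_allocation()].
#' @param category_allocation See [default_death_category_allocation()].
#' @param period_years Start year of each period band (3-year bands).
#' @param mode "exact" reproduces the allocation deterministically; "sampled"
#'   redraws the joint stratum counts multinomially.
#' @param seed Integer seed.
#' @return A list of class `death_cohort_spec`.
#' @export
death_cohort_spec <- function(match_allocation = default_death_match_allocation(),
                              category_allocation = default_death_category_allocation(),
                              period_years = c(2001L, 2004L, 2007L),
                              mode = c("exact", "sampled"), seed = 42L) {
  mode <- match.arg(mode)
  src_match <- match_allocation %>%
    dplyr::count(.data$source, wt = .data$n, name = "n_match")
  src_cat <- category_allocation %>%
    dplyr::filter(.data$category != "none") %>%
    dplyr::mutate(source = ifelse(.data$source == "coded", "coded", "freetext")) %>%
    dplyr::count(.data$source, wt = .data$n, name = "n_cat")
  chk <- dplyr::full_join(src_match, src_cat, by = "source")
  if (any(is.na(chk$n_match) | is.na(chk$n_cat) | chk$n_match != chk$n_cat)) {
    stop("match and category allocations disagree on per-source totals")
  }
  structure(list(match_allocation = match_allocation,
                 category_allocation = category_allocation,
                 period_years = as.integer(period_years),
                 mode = mode, seed = as.integer(seed)),
            class = "death_cohort_spec")
}

# Pick, for each ICD-10 code, the Read code and term used to record it:
# the lowest diagnosis code in the terminology whose core maps to that code.
icd_to_read_lookup <- function(resources) {
  stopifnot(!is.null(resources$icd_map))
  resources$terminology %>%
    dplyr::filter(.data$is_diagnosis) %>%
    dplyr::mutate(core = read_core(.data$code)) %>%
    dplyr::inner_join(resources$icd_map, by = c(core = "read_code")) %>%
    dplyr::group_by(.data$icd10) %>%
    dplyr::arrange(.data$code, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::select("icd10", "code", "term")
}

#' Generate a synthetic death cohort
#'
#' Produces a structured post-death event table, a free-text note table and
#' a death-registry gold-standard table such that the cause-of-death
#' pipeline (engine, categorisation, candidate selection, underlying-cause
#' selection, registry comparison) reproduces the specification's recording
#' categories and match-level allocation. Certificate entries whose
#' primary-care cause is an acute myocardial infarction are written as
#' two-line certificates (1a heart failure, 1b myocardial infarction) so the
#' General Principle of underlying-cause selection is exercised; all other
#' certificates are single-line.
#'
#' @param spec A [death_cohort_spec()].
#' @param resources A `notecoder_resources` list.
#' @return A list with `events` (patient_id, event_date, code, source,
#'   cert_line), `notes` (patient_id, note_date, text) and `registry`
#'   (patient_id, death_date, registry_underlying).
#' @export
generate_death_cohort <- function(spec = death_cohort_spec(),
                                  resources = default_resources()) {
  stopifnot(inherits(spec, "death_cohort_spec"))
  set.seed(spec$seed)
  lk <- icd_to_read_lookup(resources)
  to_read <- function(icd) {
    i <- match(icd, lk$icd10)
    if (any(is.na(i))) stop("no Read entry records ICD-10 code(s): ",
                            paste(unique(icd[is.na(i)]), collapse = ", "))
    lk[i, ]
  }

  match_alloc <- spec$match_allocation
  cat_alloc <- spec$category_allocation
  if (spec$mode == "sampled") {
    # redraw the joint counts over all strata (including the no-cause cells)
    probs <- c(match_alloc$n, cat_alloc$n[cat_alloc$category == "none"])
    total <- sum(probs)
    draw <- as.integer(stats::rmultinom(1, total, probs)[, 1])
    match_alloc$n <- draw[seq_len(nrow(match_alloc))]
    cat_alloc$n[cat_alloc$category == "none"] <-
      draw[nrow(match_alloc) + seq_len(sum(cat_alloc$category == "none"))]
    # rescale per-source category cells to the redrawn source totals
    for (s in c("coded", "freetext")) {
      tgt <- sum(match_alloc$n[match_alloc$source == s])
      sel <- cat_alloc$category != "none" & cat_alloc$source == s
      cur <- cat_alloc$n[sel]
      scaled <- floor(cur * tgt / sum(cur))
      rem <- tgt - sum(scaled)
      if (rem > 0) scaled[seq_len(rem)] <- scaled[seq_len(rem)] + 1L
      cat_alloc$n[sel] <- as.integer(scaled)
    }
  }

  # expand match strata into cases, exact matches first within each source
  cases <- match_alloc[rep(seq_len(nrow(match_alloc)), match_alloc$n),
                       c("source", "gold_icd", "pc_icd")]
  cases <- cases %>%
    dplyr::mutate(exact = .data$gold_icd == .data$pc_icd) %>%
    dplyr::arrange(.data$source, -.data$exact)

  # assign recording categories honouring the per-category exact quotas
  quotas <- death_exact_by_category()
  assigned <- list()
  for (s in c("coded", "freetext")) {
    cs <- cases[cases$source == s, ]
    ex_pool <- which(cs$exact)
    nx_pool <- which(!cs$exact)
    for (categ in c("transcribed_certificate", "explicit_statement", "implied_diagnosis")) {
      n_cat <- sum(cat_alloc$n[cat_alloc$category == categ & cat_alloc$source == s])
      q <- quotas$n_exact[quotas$source == s & quotas$category == categ]
      q <- min(q, length(ex_pool), n_cat)
      n_nx <- min(n_cat - q, length(nx_pool))
      # under sampled counts a pool can run dry; fill from the other pool
      q <- min(q + (n_cat - q - n_nx), length(ex_pool))
      take_ex <- ex_pool[seq_len(q)]
      take_nx <- nx_pool[seq_len(n_nx)]
      ex_pool <- ex_pool[setdiff(seq_along(ex_pool), seq_len(q))]
      nx_pool <- nx_pool[setdiff(seq_along(nx_pool), seq_len(n_nx))]
      rows <- cs[c(take_ex, take_nx), ]
      rows$category <- categ
      # distribute across periods in allocation order
      per <- cat_alloc[cat_alloc$category == categ & cat_alloc$source == s, ]
      rows$period <- rep(per$period, per$n)
      assigned[[length(assigned) + 1]] <- rows
    }
  }
  cases <- dplyr::bind_rows(assigned)

  none <- cat_alloc[cat_alloc$category == "none", ]
  none_cases <- tibble::tibble(
    source = "none",
    gold_icd = rep_len(c("I219", "C349", "I639", "J189", "R54X"), sum(none$n)),
    pc_icd = NA_character_, exact = FALSE, category = "none",
    period = rep(none$period, none$n)
  )
  cases <- dplyr::bind_rows(cases, none_cases)
  n_cases <- nrow(cases)
  cases$patient_id <- sprintf("d%04d", seq_len(n_cases))
  cases <- cases %>%
    dplyr::group_by(.data$period) %>%
    dplyr::mutate(death_date = as.Date(sprintf(
      "%04d-01-01", spec$period_years[.data$period[1]] + (dplyr::row_number() %% 3)
    )) + (dplyr::row_number() %% 300)) %>%
    dplyr::ungroup()

  registry <- cases %>%
    dplyr::transmute(patient_id = .data$patient_id, death_date = .data$death_date,
                     registry_underlying = .data$gold_icd)

  rec <- cases[cases$category != "none", ]
  rd <- to_read(rec$pc_icd)
  rec$read_code <- rd$code
  rec$term <- rd$term
  two_line <- rec$pc_icd == "I219" & rec$category == "transcribed_certificate"

  ev <- list(); nt <- list()
  # structured records
  st <- rec[rec$source == "coded", ]
  if (nrow(st) > 0) {
    tl <- st$pc_icd == "I219" & st$category == "transcribed_certificate"
    cert <- st$category == "transcribed_certificate"
    ev[[1]] <- tibble::tibble(
      patient_id = st$patient_id, event_date = st$death_date + 1,
      code = st$read_code, source = "structured",
      cert_line = ifelse(cert, ifelse(tl, "1b", "1a"), NA_character_)
    )
    if (any(tl)) {
      ev[[2]] <- tibble::tibble(
        patient_id = st$patient_id[tl], event_date = st$death_date[tl] + 1,
        code = "G58z.00", source = "structured", cert_line = "1a")
    }
    expl <- st$category == "explicit_statement"
    if (any(expl)) {
      ev[[3]] <- tibble::tibble(
        patient_id = st$patient_id[expl], event_date = st$death_date[expl] + 1,
        code = resources$config$cause_marker_code, source = "structured",
        cert_line = NA_character_)
    }
  }
  # free-text records
  ft <- rec[rec$source == "freetext", ]
  if (nrow(ft) > 0) {
    tl <- ft$pc_icd == "I219" & ft$category == "transcribed_certificate"
    text <- dplyr::case_when(
      ft$category == "transcribed_certificate" & tl ~
        "1a heart failure 1b acute myocardial infarction nos",
      ft$category == "transcribed_certificate" ~ paste("1a", ft$term),
      ft$category == "explicit_statement" ~ paste("cause of death:", ft$term),
      TRUE ~ ft$term
    )
    nt[[1]] <- tibble::tibble(
      patient_id = ft$patient_id, note_date = ft$death_date + 1, text = text)
  }

  list(
    events = if (length(ev) > 0) {
      dplyr::bind_rows(ev) %>%
        dplyr::arrange(.data$patient_id, .data$event_date, .data$cert_line, .data$code)
    } else {
      tibble::tibble(patient_id = character(0), event_date = as.Date(character(0)),
                     code = character(0), source = character(0), cert_line = character(0))
    },
    notes = if (length(nt) > 0) dplyr::bind_rows(nt) %>% dplyr::arrange(.data$patient_id) else
      tibble::tibble(patient_id = character(0), note_date = as.Date(character(0)), text = character(0)),
    registry = registry
  )
}
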