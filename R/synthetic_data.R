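# Concept pool used by the note generator. Every phrase resolves to exactly
# this code when passed through the engine on the bundled terminology (ties
# such as "chest pain" resolve to the lexicographically lowest code).
note_template_pool <- function() {
  tibble::tribble(
    ~phrase,                        ~code,
    "chest pain",                   "182..00",
    "breathlessness",               "173..00",
    "angina pectoris",              "G33..00",
    "pneumonia",                    "H26..00",
    "oedema",                       "R023.00",
    "vomiting",                     "199..00",
    "fever",                        "R006200",
    "asthma",                       "H33..00",
    "diabetes mellitus",            "C10..00",
    "urinary tract infection",      "K190.00",
    "atrial fibrillation",          "G573.00",
    "stroke",                       "G66..00",
    "carcinoma of breast",          "B34..00",
    "heart failure",                "G58z.00",
    "acute myocardial infarction nos", "G30z.00"
  )
}

filler_sentences <- c("seen today", "reviewed in clinic", "feels well",
                      "advice given", "plan to monitor")

#' Specification for a synthetic note corpus
#'
#' @param n_notes Number of notes.
#' @param negation_rate,suspicion_rate,history_rate Probability that a note's
#'   concept mention is negated, suspected, or historical (the remainder are
#'   current conditions). Must sum to at most 1.
#' @param misspelling_rate Probability that a word of the concept phrase is
#'   corrupted by one letter deletion or substitution (the two operations the
#'   engine's single insertion/substitution corrector can reverse).
#' @param numeric_result_rate Probability that a note carries an additional
#'   quantitative result sentence (pulse or blood pressure).
#' @param seed Integer seed; the same spec always yields the same corpus.
#' @return A list of class `note_spec`.
#' @export
note_spec <- function(n_notes = 100, negation_rate = 0.15,
                      suspicion_rate = 0.05, history_rate = 0.1,
                      misspelling_rate = 0.05, numeric_result_rate = 0.2,
                      seed = 42L) {
  rates <- c(negation_rate, suspicion_rate, history_rate,
             misspelling_rate, numeric_result_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (negation_rate + suspicion_rate + history_rate > 1) {
    stop("attribute rates must sum to at most 1")
  }
  structure(list(n_notes = as.integer(n_notes), negation_rate = negation_rate,
                 suspicion_rate = suspicion_rate, history_rate = history_rate,
                 misspelling_rate = misspelling_rate,
                 numeric_result_rate = numeric_result_rate,
                 seed = as.integer(seed)), class = "note_spec")
}

# Corrupt one word by a single deletion or substitution such that the
# engine's corrector provably recovers it; returns the word unchanged when no
# reversible corruption exists.
corrupt_word <- function(word, resources) {
  if (nchar(word) < 5) return(word)
  chars <- strsplit(word, "")[[1]]
  n <- length(chars)
  cands <- character(0)
  for (i in seq_len(n)) cands <- c(cands, paste(chars[-i], collapse = ""))
  for (i in seq_len(n)) {
    l <- sample(setdiff(letters, chars[i]), 1)
    tmp <- chars; tmp[i] <- l
    cands <- c(cands, paste(tmp, collapse = ""))
  }
  cands <- sample(cands)
  for (cand in cands) {
    if (cand %in% resources$medical_words || cand %in% resources$nonmedical_words) next
    if (correct_spelling(cand, resources) == word) return(cand)
  }
  word
}

#' Generate a synthetic note corpus with gold annotations
#'
#' Builds notes from phrase templates over the toy terminology: plain,
#' negated, suspected and historical concept mentions, optional filler
#' sentences, and optional quantitative-result sentences. Misspellings are
#' injected only as corruptions the engine's corrector can reverse, so the
#' gold annotations stay exact. The same spec (including seed) always
#' produces a byte-identical corpus.
#'
#' @param spec A [note_spec()].
#' @param resources A `notecoder_resources` list.
#' @return A list with `notes` (tibble: patient_id, note_date, text) and
#'   `gold` (tibble: note_idx, code, attribute, numeric_value,
#'   numeric_value2).
#' @export
generate_notes <- function(spec, resources = default_resources()) {
  stopifnot(inherits(spec, "note_spec"))
  set.seed(spec$seed)
  pool <- note_template_pool()
  n <- spec$n_notes

  concept <- sample(nrow(pool), n, replace = TRUE)
  u <- stats::runif(n)
  attribute <- dplyr::case_when(
    u < spec$negation_rate ~ "absent",
    u < spec$negation_rate + spec$suspicion_rate ~ "suspected",
    u < spec$negation_rate + spec$suspicion_rate + spec$history_rate ~ "history",
    TRUE ~ "current_or_previous"
  )
  neg_cue <- sample(c("no", "denies"), n, replace = TRUE)
  susp_cue <- sample(c("possible", "?"), n, replace = TRUE)
  hist_cue <- sample(c("previous", "h/o"), n, replace = TRUE)
  with_filler <- stats::runif(n) < 0.5
  with_numeric <- stats::runif(n) < spec$numeric_result_rate
  numeric_kind <- sample(c("pulse", "bp"), n, replace = TRUE)
  pulse_val <- sample(55:110, n, replace = TRUE)
  sys_val <- sample(100:180, n, replace = TRUE)
  dia_val <- sample(60:100, n, replace = TRUE)
  fillers <- sample(filler_sentences, n, replace = TRUE)

  notes <- character(n)
  gold <- vector("list", n)
  for (i in seq_len(n)) {
    phrase <- pool$phrase[concept[i]]
    if (spec$misspelling_rate > 0) {
      words <- strsplit(phrase, " ")[[1]]
      hit <- stats::runif(length(words)) < spec$misspelling_rate
      for (j in which(hit)) words[j] <- corrupt_word(words[j], resources)
      phrase <- paste(words, collapse = " ")
    }
    sent <- switch(attribute[i],
      absent = paste(neg_cue[i], phrase),
      suspected = if (susp_cue[i] == "?") paste0("?", phrase) else paste(susp_cue[i], phrase),
      history = paste(hist_cue[i], phrase),
      phrase
    )
    parts <- character(0)
    if (with_filler[i]) parts <- c(parts, fillers[i])
    parts <- c(parts, sent)
    g <- tibble::tibble(note_idx = i, code = pool$code[concept[i]],
                        attribute = attribute[i],
                        numeric_value = NA_real_, numeric_value2 = NA_real_)
    if (with_numeric[i]) {
      if (numeric_kind[i] == "pulse") {
        parts <- c(parts, paste("pulse", pulse_val[i]))
        g <- dplyr::bind_rows(g, tibble::tibble(
          note_idx = i, code = "242..00", attribute = "current_or_previous",
          numeric_value = as.numeric(pulse_val[i]), numeric_value2 = NA_real_))
      } else {
        parts <- c(parts, paste0("bp ", sys_val[i], "/", dia_val[i]))
        g <- dplyr::bind_rows(g, tibble::tibble(
          note_idx = i, code = "246..00", attribute = "current_or_previous",
          numeric_value = as.numeric(sys_val[i]),
          numeric_value2 = as.numeric(dia_val[i])))
      }
    }
    notes[i] <- paste0(paste(parts, collapse = ". "), ".")
    gold[[i]] <- g
  }

  list(
    notes = tibble::tibble(
      patient_id = sprintf("n%05d", seq_len(n)),
      note_date = as.Date("2005-01-01") + (seq_len(n) %% 365),
      text = notes
    ),
    gold = dplyr::bind_rows(gold)
  )
}

#' Default MI-cohort confusion allocation
#'
#' Per-stratum patient counts for gold MI subtype x primary-care source x
#' subtype call, for the registry-linked patients of the default cohort
#' (315 STEMI, 293 NSTEMI).
#'
#' @return A tibble with columns `gold`, `source`, `call`, `n`.
#' @export
default_subtype_allocation <- function() {
  tibble::tribble(
    ~gold,    ~source,      ~call,          ~n,
    "STEMI",  "structured", "STEMI",         41L,
    "STEMI",  "structured", "NSTEMI",         6L,
    "NSTEMI", "structured", "STEMI",          6L,
    "NSTEMI", "structured", "NSTEMI",        96L,
    "STEMI",  "freetext",   "STEMI",         13L,
    "STEMI",  "freetext",   "NSTEMI",         5L,
    "NSTEMI", "freetext",   "STEMI",          5L,
    "NSTEMI", "freetext",   "NSTEMI",        23L,
    "STEMI",  "none",       "unclassified", 250L,
    "NSTEMI", "none",       "unclassified", 163L
  )
}

#' Default symptom/investigation recording allocation
#'
#' Patient counts with a structured record and with a record in either source
#' for each symptom or investigation item, with its counting window in days
#' relative to the MI date.
#'
#' @return A tibble with columns `item`, `from`, `to`, `n_structured`,
#'   `n_either`.
#' @export
default_symptom_allocation <- function() {
  tibble::tribble(
    ~item,             ~from, ~to, ~n_structured, ~n_either,
    "pulse_rate",        -90L, 90L,  323L,  634L,
    "blood_pressure",    -90L, 90L, 1557L, 1609L,
    "lv_function",       -90L, 90L,  115L,  309L,
    "angiogram",         -90L, 90L,   26L,  198L,
    "irregular_pulse",   -90L, 90L,    2L,    6L,
    "atrial_fibrillation", -90L, 90L, 121L,  153L,
    "chest_pain_7d",      -7L,  0L,  378L,  543L,
    "chest_pain_90d",    -90L,  0L,  455L,  642L,
    "breathlessness_7d",  -7L,  0L,   62L,  102L,
    "breathlessness_90d", -90L, 0L,  125L,  196L
  )
}

# item -> (structured event code, free-text phrase)
symptom_item_templates <- function() {
  tibble::tribble(
    ~item,                  ~code,     ~phrase,
    "pulse_rate",           "242..00", "pulse 88",
    "blood_pressure",       "246..00", "bp 130/85",
    "lv_function",          "G581.13", "impaired left ventricular function",
    "angiogram",            "3887.00", "coronary angiogram",
    "irregular_pulse",      "2432.00", "irregular pulse",
    "atrial_fibrillation",  "G573.00", "atrial fibrillation",
    "chest_pain",           "182..00", "chest pain",
    "breathlessness",       "173..00", "shortness of breath"
  )
}

#' Specification for a synthetic MI cohort
#'
#' Defaults parameterise the generator with the reported contingency
#' structure: the subtype confusion for the registry-linked patients and the
#' per-item symptom/investigation recording counts.
#'
#' @param n_patients Cohort size.
#' @param subtype_allocation See [default_subtype_allocation()].
#' @param symptom_allocation See [default_symptom_allocation()].
#' @param mode "exact" reproduces the allocation counts deterministically;
#'   "sampled" draws each patient's stratum from the corresponding
#'   multinomial/binomial probabilities.
#' @param seed Integer seed (used in "sampled" mode and for date jitter).
#' @return A list of class `mi_cohort_spec`.
#' @export
mi_cohort_spec <- function(n_patients = 2000L,
                           subtype_allocation = default_subtype_allocation(),
                           symptom_allocation = default_symptom_allocation(),
                           mode = c("exact", "sampled"), seed = 42L) {
  mode <- match.arg(mode)
  tot <- sum(subtype_allocation$n)
  if (tot > n_patients) stop("subtype allocation exceeds cohort size")
  if (any(symptom_allocation$n_either > n_patients) ||
      any(symptom_allocation$n_structured > symptom_allocation$n_either)) {
    stop("inconsistent symptom allocation totals")
  }
  structure(list(n_patients = as.integer(n_patients),
                 subtype_allocation = subtype_allocation,
                 symptom_allocation = symptom_allocation,
                 mode = mode, seed = as.integer(seed)),
            class = "mi_cohort_spec")
}

#' Generate a synthetic MI cohort
#'
#' Produces a structured event table, a free-text note table and a registry
#' gold-standard subtype table such that running the engine plus the subtype
#' classifier and the symptom tabulation over them reproduces the
#' specification's allocation (exactly in "exact" mode, up to sampling error
#' in "sampled" mode). Registry-linked patients come first; subtype evidence
#' is placed within 30 days after the MI date, symptom evidence at fixed
#' offsets inside each item's window.
#'
#' @param spec An [mi_cohort_spec()].
#' @return A list with `events` (patient_id, event_date, code, source),
#'   `notes` (patient_id, note_date, text), `gold` (patient_id, mi_date,
#'   gold_subtype) and `mi_dates` (patient_id, mi_date for all patients).
#' @export
generate_mi_cohort <- function(spec = mi_cohort_spec()) {
  stopifnot(inherits(spec, "mi_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  ids <- sprintf("p%04d", seq_len(n))
  mi_dates <- tibble::tibble(
    patient_id = ids,
    mi_date = as.Date("2005-01-01") + (seq_len(n) %% 365)
  )

  alloc <- spec$subtype_allocation
  if (spec$mode == "sampled") {
    alloc <- alloc %>%
      dplyr::group_by(.data$gold) %>%
      dplyr::mutate(n = as.integer(stats::rmultinom(1, sum(.data$n), .data$n)[, 1])) %>%
      dplyr::ungroup()
  }
  strata <- alloc[rep(seq_len(nrow(alloc)), alloc$n), c("gold", "source", "call")]
  n_gold <- nrow(strata)
  strata$patient_id <- ids[seq_len(n_gold)]
  gold <- dplyr::left_join(strata, mi_dates, by = "patient_id") %>%
    dplyr::transmute(patient_id = .data$patient_id, mi_date = .data$mi_date,
                     gold_subtype = .data$gold)

  ev <- list(); nt <- list()
  sub_struct <- strata[strata$source == "structured", ]
  if (nrow(sub_struct) > 0) {
    md <- mi_dates$mi_date[match(sub_struct$patient_id, mi_dates$patient_id)]
    ev[[1]] <- tibble::tibble(
      patient_id = sub_struct$patient_id,
      event_date = md + 2,
      code = ifelse(sub_struct$call == "STEMI", "G30X.00", "G307100"),
      source = "structured"
    )
  }
  sub_ft <- strata[strata$source == "freetext", ]
  if (nrow(sub_ft) > 0) {
    md <- mi_dates$mi_date[match(sub_ft$patient_id, mi_dates$patient_id)]
    nt[[1]] <- tibble::tibble(
      patient_id = sub_ft$patient_id,
      note_date = md + 3,
      text = ifelse(sub_ft$call == "STEMI", "stemi", "nstemi")
    )
  }

  # symptom/investigation recording: nested windows (7d inside 90d) are
  # realised with four disjoint patient blocks; flat +/-90d items with two.
  tmpl <- symptom_item_templates()
  sympt <- spec$symptom_allocation
  base_item <- sub("_(7|90)d$", "", sympt$item)
  pick <- function(n_pat, p) {
    if (spec$mode == "exact") seq_len(n_pat) else which(stats::runif(n) < p)
  }
  for (i in seq_len(nrow(sympt))) {
    if (grepl("_90d$", sympt$item[i])) next  # handled with the 7d row
    it <- base_item[i]
    trow <- tmpl[tmpl$item == it, ]
    if (grepl("_7d$", sympt$item[i])) {
      row90 <- sympt[base_item == it & grepl("_90d$", sympt$item), ]
      s7 <- sympt$n_structured[i]; e7 <- sympt$n_either[i]
      s90 <- row90$n_structured; e90 <- row90$n_either
      if (spec$mode == "sampled") {
        s7 <- stats::rbinom(1, n, s7 / n); s90 <- s7 + stats::rbinom(1, n, (row90$n_structured - sympt$n_structured[i]) / n)
        e7 <- s7 + stats::rbinom(1, n, (sympt$n_either[i] - sympt$n_structured[i]) / n)
        e90 <- e7 + stats::rbinom(1, n, (row90$n_either - row90$n_structured - (sympt$n_either[i] - sympt$n_structured[i])) / n)
        t90_extra <- e90 - e7
      } else {
        t90_extra <- (e90 - s90) - (e7 - s7)
      }
      blocks <- list(
        list(idx = seq_len(s7), offset = -3L, structured = TRUE),
        list(idx = seq_len(s90 - s7) + s7, offset = -40L, structured = TRUE),
        list(idx = seq_len(e7 - s7) + s90, offset = -3L, structured = FALSE),
        list(idx = seq_len(t90_extra) + s90 + (e7 - s7), offset = -40L, structured = FALSE)
      )
    } else {
      ns <- sympt$n_structured[i]; ne <- sympt$n_either[i]
      if (spec$mode == "sampled") {
        ns <- stats::rbinom(1, n, ns / n)
        ne <- ns + stats::rbinom(1, n, (sympt$n_either[i] - sympt$n_structured[i]) / n)
      }
      blocks <- list(
        list(idx = seq_len(ns), offset = -10L, structured = TRUE),
        list(idx = seq_len(ne - ns) + ns, offset = 5L, structured = FALSE)
      )
    }
    for (b in blocks) {
      if (length(b$idx) == 0) next
      pid <- ids[b$idx]
      dt <- mi_dates$mi_date[b$idx] + b$offset
      if (b$structured) {
        ev[[length(ev) + 1]] <- tibble::tibble(
          patient_id = pid, event_date = dt, code = trow$code,
          source = "structured")
      } else {
        nt[[length(nt) + 1]] <- tibble::tibble(
          patient_id = pid, note_date = dt, text = trow$phrase)
      }
    }
  }

  list(
    events = dplyr::bind_rows(ev) %>% dplyr::arrange(.data$patient_id, .data$event_date, .data$code),
    notes = dplyr::bind_rows(nt) %>% dplyr::arrange(.data$patient_id, .data$note_date, .data$text),
    gold = gold,
    mi_dates = mi_dates
  )
}
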