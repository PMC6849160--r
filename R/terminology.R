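#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Normalise printed code forms: unicode ellipsis to ASCII dots, trim whitespace.
normalise_code <- function(code) {
  code <- stringr::str_trim(code)
  code <- stringr::str_replace_all(code, "…", "...")
  code
}

# Read-like codes: 5-character core (dot-padded) + 2-character term suffix,
# e.g. "G30z.00", "G307100", "1M...00".
is_valid_read_code <- function(code) {
  stringr::str_detect(code, "^[A-Za-z0-9][A-Za-z0-9.]{4}[A-Za-z0-9]{2}$")
}

read_core <- function(code) substr(code, 1L, 5L)

is_valid_icd10 <- function(code) {
  stringr::str_detect(code, "^[A-Z][0-9]{2}[0-9X]?$")
}

#' Test whether a Read-like code is a diagnosis code
#'
#' Read v2 organises diagnoses into chapters keyed by an upper-case initial
#' letter; administrative, history/symptom and test-result codes begin with a
#' digit or lower-case character. A code is a diagnosis code if and only if
#' its first character is an upper-case letter.
#'
#' @param code Character vector of Read-like codes (7 characters: 5-character
#'   core padded with dots plus a 2-character term suffix).
#' @return Logical vector.
#' @examples
#' is_diagnosis_code(c("G30z.00", "8H3Z.00", "42Z7.00"))
#' @export
is_diagnosis_code <- function(code) {
  code <- normalise_code(code)
  bad <- !is_valid_read_code(code)
  if (any(bad)) {
    stop("malformed Read-like code(s): ", paste(unique(code[bad]), collapse = ", "))
  }
  stringr::str_detect(code, "^[A-Z]")
}

# WHO ICD-10 chapter boundaries, extended so that every syntactically valid
# three-character category A00-Z99 falls in exactly one chapter (the small
# unassigned gaps, e.g. D49, are absorbed into the adjacent chapter).
icd10_chapter_table <- function() {
  tibble::tribble(
    ~chapter, ~from,  ~to,
    "I",      "A00",  "B99",
    "II",     "C00",  "D48",
    "III",    "D49",  "D99",
    "IV",     "E00",  "E99",
    "V",      "F00",  "F99",
    "VI",     "G00",  "G99",
    "VII",    "H00",  "H59",
    "VIII",   "H60",  "H99",
    "IX",     "I00",  "I99",
    "X",      "J00",  "J99",
    "XI",     "K00",  "K99",
    "XII",    "L00",  "L99",
    "XIII",   "M00",  "M99",
    "XIV",    "N00",  "N99",
    "XV",     "O00",  "O99",
    "XVI",    "P00",  "P99",
    "XVII",   "Q00",  "Q99",
    "XVIII",  "R00",  "R99",
    "XIX",    "S00",  "T99",
    "XXII",   "U00",  "U99",
    "XX",     "V00",  "Y99",
    "XXI",    "Z00",  "Z99"
  )
}

#' ICD-10 chapter of a code
#'
#' Assigns the WHO ICD-10 chapter (roman numeral I..XXII) from the
#' three-character category of the code using a built-in boundary table.
#'
#' @param icd10 Character vector of ICD-10 codes (3 or 4 characters, e.g.
#'   "I219", "F03X", "C50").
#' @return Character vector of roman-numeral chapter identifiers.
#' @examples
#' icd10_chapter(c("I219", "C509", "F03X"))
#' @export
icd10_chapter <- function(icd10) {
  icd10 <- toupper(stringr::str_trim(icd10))
  ok <- stringr::str_detect(icd10, "^[A-Z][0-9]{2}")
  if (any(!ok)) {
    stop("unmappable ICD-10 code(s): ", paste(unique(icd10[!ok]), collapse = ", "))
  }
  cat3 <- substr(icd10, 1L, 3L)
  tab <- icd10_chapter_table()
  idx <- vapply(cat3, function(x) {
    which(x >= tab$from & x <= tab$to)[1]
  }, integer(1))
  if (any(is.na(idx))) {
    stop("unmappable ICD-10 code(s): ", paste(unique(cat3[is.na(idx)]), collapse = ", "))
  }
  unname(tab$chapter[idx])
}

#' Cause-of-death group membership
#'
#' Tests whether an ICD-10 code belongs to one of the three reported cause
#' groups: coronary heart disease (I20-I25), cerebrovascular disease
#' (F01 plus I60-I69) or cancer (C00-C97). Membership is decided on the
#' three-character category.
#'
#' @param icd10 Character vector of ICD-10 codes.
#' @param group One of "coronary", "cerebrovascular", "cancer".
#' @return Logical vector.
#' @examples
#' in_cause_group("I219", "coronary")
#' in_cause_group("F019", "cerebrovascular")
#' @export
in_cause_group <- function(icd10, group) {
  group <- match.arg(group, c("coronary", "cerebrovascular", "cancer"))
  icd10 <- toupper(stringr::str_trim(icd10))
  ok <- stringr::str_detect(icd10, "^[A-Z][0-9]{2}")
  if (any(!ok)) {
    stop("unmappable ICD-10 code(s): ", paste(unique(icd10[!ok]), collapse = ", "))
  }
  cat3 <- substr(icd10, 1L, 3L)
  switch(group,
    coronary = cat3 >= "I20" & cat3 <= "I25",
    cerebrovascular = cat3 == "F01" | (cat3 >= "I60" & cat3 <= "I69"),
    cancer = cat3 >= "C00" & cat3 <= "C97"
  )
}

split_words <- function(term) {
  stringr::str_split(term, "[^a-z0-9]+")[[1]] %>% purrr::discard(~ .x == "")
}

read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop(basename(path), ": missing required column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Engine configuration
#'
#' Tunable parameters of the coding engine, with defaults. All scoring weights
#' and thresholds live here so that behaviour is fully declared.
#'
#' @param threshold Minimum match score for a candidate to be emitted.
#' @param w_cov Weight on term-word coverage in the match score.
#' @param w_syn Penalty per synonym substitution.
#' @param w_sp Penalty per spelling correction.
#' @param max_substitutions Maximum synonym substitutions per candidate.
#' @param max_span Maximum number of word tokens in a match span.
#' @param min_correct_len Minimum word length for spelling correction to be
#'   attempted (shorter strings are treated as abbreviations).
#' @param negation_scope Maximum tokens a negation/suspicion/history cue
#'   governs within a sentence.
#' @param numeric_window Maximum token distance between a measurable concept
#'   and the number bound to it.
#' @param icd10_match_chars Characters of the ICD-10 category compared for the
#'   mid-level ("same category") cause-of-death match: 3 (default) or 2.
#' @return A named list of class `notecoder_config`.
#' @export
engine_config <- function(threshold = 0.7, w_cov = 1, w_syn = 0.15, w_sp = 0.1,
                          max_substitutions = 2L, max_span = 5L,
                          min_correct_len = 4L, negation_scope = 6L,
                          numeric_window = 3L, icd10_match_chars = 3L) {
  stopifnot(threshold >= 0, threshold <= 1, icd10_match_chars %in% c(2L, 3L))
  structure(list(
    threshold = threshold, w_cov = w_cov, w_syn = w_syn, w_sp = w_sp,
    max_substitutions = as.integer(max_substitutions),
    max_span = as.integer(max_span),
    min_correct_len = as.integer(min_correct_len),
    negation_scope = as.integer(negation_scope),
    numeric_window = as.integer(numeric_window),
    icd10_match_chars = as.integer(icd10_match_chars),
    unit_vocabulary = c("mmhg", "bpm", "mmol/l", "fl", "%", "kg", "cm"),
    measurable_codes = c("242..00", "246..00", "42Z7.00", "42M..00",
                         "42N..00", "42K..00", "42J..00", "3887.00"),
    stemi_codes = c("G30X.00", "G30X000"),
    nstemi_codes = c("G307100", "G307111"),
    cause_marker_code = "9B0..00"
  ), class = "notecoder_config")
}

#' Load the terminology and its companion lookups
#'
#' Reads the Read-like terminology, the synonym table, the English lexicon and
#' (optionally) the cleanup-phrase list, the Read to ICD-10 map and the
#' causal-sequence table, and builds the derived indexes the engine needs:
#' the medical lexicon (every word appearing in any term), word frequencies,
#' and the phrase index used for matching.
#'
#' @param term_path Terminology TSV with columns `code`, `term`.
#' @param synonym_path Synonym TSV with columns `source`, `target` (each 1-3
#'   words).
#' @param lexicon_path Plain-text English lexicon, one word per line
#'   (the "non-medical" word list).
#' @param cleanup_path Optional TSV with column `phrase`: ordered list of
#'   computer-generated phrases removed before tokenisation.
#' @param icd_map_path Optional TSV with columns `read_code` (5-character
#'   core), `icd10`.
#' @param causal_path Optional TSV with columns `cause_icd10_prefix`,
#'   `consequence_icd10_prefix` describing "could give rise to" pairs used in
#'   underlying-cause selection.
#' @param config An [engine_config()] list.
#' @return A list of class `notecoder_resources` with elements `terminology`
#'   (tibble: code, term, is_diagnosis, n_words), `medical_words`,
#'   `nonmedical_words`, `word_freq`, `synonyms`, `cleanup_rules`, `icd_map`,
#'   `causal`, and `config`.
#' @examples
#' res <- default_resources()
#' nrow(res$terminology)
#' @export
load_terminology <- function(term_path, synonym_path, lexicon_path,
                             cleanup_path = NULL, icd_map_path = NULL,
                             causal_path = NULL, config = engine_config()) {
  term_df <- read_tsv_strict(term_path, c("code", "term"))
  if (nrow(term_df) == 0) stop("empty terminology file: ", term_path)

  term_df$code <- normalise_code(term_df$code)
  term_df$term <- tolower(stringr::str_trim(term_df$term))
  bad <- which(!is_valid_read_code(term_df$code) | term_df$term == "")
  if (length(bad) > 0) {
    stop("malformed terminology row at line ", bad[1] + 1L,
         " (code '", term_df$code[bad[1]], "')")
  }
  dup <- term_df %>%
    dplyr::distinct(.data$code, .data$term) %>%
    dplyr::count(.data$code) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate code with conflicting term: ", paste(dup$code, collapse = ", "))
  }
  term_df <- dplyr::distinct(term_df, .data$code, .keep_all = TRUE)

  terminology <- term_df %>%
    dplyr::mutate(
      is_diagnosis = is_diagnosis_code(.data$code),
      n_words = purrr::map_int(.data$term, ~ length(split_words(.x)))
    ) %>%
    tibble::as_tibble()

  term_words <- unlist(purrr::map(terminology$term, split_words))
  word_freq <- sort(table(term_words), decreasing = TRUE)
  medical_words <- names(word_freq)

  if (!file.exists(lexicon_path)) stop("file not found: ", lexicon_path)
  nonmedical_words <- tolower(stringr::str_trim(readLines(lexicon_path, warn = FALSE)))
  nonmedical_words <- unique(nonmedical_words[nonmedical_words != ""])

  syn_df <- read_tsv_strict(synonym_path, c("source", "target"))
  syn_df$source <- tolower(stringr::str_trim(syn_df$source))
  syn_df$target <- tolower(stringr::str_trim(syn_df$target))
  n_words_syn <- function(x) lengths(stringr::str_split(x, "\\s+"))
  bad <- which(syn_df$source == "" | syn_df$target == "" |
                 n_words_syn(syn_df$source) > 3 | n_words_syn(syn_df$target) > 3)
  if (length(bad) > 0) stop("malformed synonym row at line ", bad[1] + 1L)

  cleanup_rules <- character(0)
  if (!is.null(cleanup_path)) {
    cleanup_rules <- tolower(read_tsv_strict(cleanup_path, "phrase")$phrase)
  }

  icd_map <- NULL
  if (!is.null(icd_map_path)) {
    icd_map <- read_tsv_strict(icd_map_path, c("read_code", "icd10"))
    icd_map$read_code <- normalise_code(icd_map$read_code)
    icd_map$icd10 <- toupper(stringr::str_trim(icd_map$icd10))
    bad <- which(!is_valid_icd10(icd_map$icd10))
    if (length(bad) > 0) stop("malformed ICD-10 code in map at line ", bad[1] + 1L)
  }

  causal <- NULL
  if (!is.null(causal_path)) {
    causal <- read_tsv_strict(causal_path, c("cause_icd10_prefix", "consequence_icd10_prefix"))
  }

  res <- list(
    terminology = terminology,
    medical_words = medical_words,
    nonmedical_words = nonmedical_words,
    word_freq = word_freq,
    synonyms = tibble::as_tibble(syn_df),
    cleanup_rules = cleanup_rules,
    icd_map = icd_map,
    causal = causal,
    config = config
  )
  res$phrase_index <- build_phrase_index(terminology)
  structure(res, class = "notecoder_resources")
}

# Phrase index: every term plus every word-prefix of every term, with the
# number of term words covered. Prefix rows let spans match the head of a
# longer term at reduced coverage.
build_phrase_index <- function(terminology) {
  purrr::map_dfr(seq_len(nrow(terminology)), function(i) {
    words <- split_words(terminology$term[i])
    n <- length(words)
    tibble::tibble(
      phrase = vapply(seq_len(n), function(k) paste(words[seq_len(k)], collapse = " "), ""),
      code = terminology$code[i],
      n_matched = seq_len(n),
      n_term_words = n
    )
  })
}

#' Bundled toy resources
#'
#' Loads the small terminology, synonym table, lexicon, cleanup rules,
#' Read to ICD-10 map and causal-sequence table shipped with the package.
#'
#' @param config An [engine_config()] list.
#' @return A `notecoder_resources` list; see [load_terminology()].
#' @export
default_resources <- function(config = engine_config()) {
  ext <- function(f) system.file("extdata", f, package = "notecoder", mustWork = TRUE)
  load_terminology(
    term_path = ext("terminology.tsv"),
    synonym_path = ext("synonyms.tsv"),
    lexicon_path = ext("lexicon.txt"),
    cleanup_path = ext("cleanup_rules.tsv"),
    icd_map_path = ext("read_icd10.tsv"),
    causal_path = ext("causal_sequence.tsv"),
    config = config
  )
}

# Map a full Read-like code to ICD-10 via its 5-character core.
map_read_to_icd10 <- function(code, resources) {
  stopifnot(!is.null(resources$icd_map))
  core <- read_core(normalise_code(code))
  out <- resources$icd_map$icd10[match(core, resources$icd_map$read_code)]
  if (any(is.na(out))) {
    stop("no ICD-10 mapping for Read code(s): ",
         paste(unique(code[is.na(out)]), collapse = ", "))
  }
  out
}
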