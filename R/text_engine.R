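#' Remove computer-generated boilerplate phrases
#'
#' Strips each phrase in `cleanup_rules` (an ordered list of literal,
#' case-insensitive phrases) from the text, collapsing the surrounding
#' whitespace. Removal is idempotent: `clean_text(clean_text(x)) ==
#' clean_text(x)`.
#'
#' @param text Character vector of raw note texts.
#' @param cleanup_rules Character vector of literal phrases, applied in order.
#' @return Character vector of cleaned texts.
#' @examples
#' clean_text("End of report. chest pain settled", "end of report.")
#' @export
clean_text <- function(text, cleanup_rules = character(0)) {
  text[is.na(text)] <- ""
  out <- text
  for (rule in cleanup_rules) {
    out <- stringr::str_replace_all(out, stringr::fixed(rule, ignore_case = TRUE), " ")
  }
  out <- stringr::str_squish(out)
  out
}

month_abbrevs <- c(jan = 1, feb = 2, mar = 3, apr = 4, may = 5, jun = 6,
                   jul = 7, aug = 8, sep = 9, oct = 10, nov = 11, dec = 12)

token_pattern <- paste(
  "\\d{1,2}[/.]\\d{1,2}[/.]\\d{2,4}",
  "\\d{1,2}\\s+(?:jan|feb|mar|apr|may|jun|jul|aug|sep|oct|nov|dec)[a-z]*\\s+\\d{4}",
  "\\d{2,3}/\\d{2,3}",
  "1[abc](?![a-z0-9])",
  "\\d+(?:\\.\\d+)?",
  "[a-z]+(?:[-'/][a-z]+)*",
  "[?.;!,]",
  sep = "|"
)

parse_numeric_date <- function(surface) {
  parts <- as.integer(stringr::str_split(surface, "[/.]")[[1]])
  d <- parts[1]; m <- parts[2]; y <- parts[3]
  if (y < 100) y <- ifelse(y < 50, 2000 + y, 1900 + y)
  if (is.na(d) || is.na(m) || m < 1 || m > 12 || d < 1 || d > 31) return(as.Date(NA))
  out <- suppressWarnings(as.Date(sprintf("%04d-%02d-%02d", y, m, d)))
  out
}

parse_text_date <- function(surface) {
  bits <- stringr::str_split(stringr::str_squish(surface), "\\s+")[[1]]
  d <- as.integer(bits[1])
  m <- unname(month_abbrevs[substr(bits[2], 1, 3)])
  y <- as.integer(bits[3])
  if (is.na(m)) return(as.Date(NA))
  suppressWarnings(as.Date(sprintf("%04d-%02d-%02d", y, m, d)))
}

# Tokenise a vector of (already cleaned) texts into one long tibble.
# Newlines always terminate a sentence; '.' ';' '!' punct tokens do too.
tokenize_corpus <- function(text) {
  text <- tolower(text)
  text <- stringr::str_replace_all(text, "\\n", " . ")
  tok_list <- stringr::str_extract_all(text, token_pattern)
  n_tok <- lengths(tok_list)
  if (sum(n_tok) == 0) {
    return(tibble::tibble(note_idx = integer(0), position = integer(0),
                          kind = character(0), surface = character(0),
                          value = numeric(0), date_value = as.Date(character(0)),
                          sentence = integer(0), pair_id = integer(0)))
  }
  df <- tibble::tibble(
    note_idx = rep(seq_along(text), n_tok),
    surface = unlist(tok_list)
  )
  is_slash_date <- stringr::str_detect(df$surface, "^\\d{1,2}[/.]\\d{1,2}[/.]\\d{2,4}$")
  is_text_date <- stringr::str_detect(df$surface, "^\\d{1,2}\\s")
  is_pair <- stringr::str_detect(df$surface, "^\\d{2,3}/\\d{2,3}$")
  is_number <- stringr::str_detect(df$surface, "^\\d+(\\.\\d+)?$")
  is_punct <- stringr::str_detect(df$surface, "^[?.;!,]$")

  df$kind <- "word"
  df$kind[is_number] <- "number"
  df$kind[is_punct] <- "punct"
  df$value <- NA_real_
  df$value[is_number] <- as.numeric(df$surface[is_number])
  df$date_value <- as.Date(NA)

  idx_date <- which(is_slash_date | is_text_date)
  if (length(idx_date) > 0) {
    parsed <- as.Date(vapply(idx_date, function(i) {
      d <- if (is_slash_date[i]) parse_numeric_date(df$surface[i]) else parse_text_date(df$surface[i])
      as.numeric(d)
    }, numeric(1)), origin = "1970-01-01")
    ok <- !is.na(parsed)
    df$kind[idx_date[ok]] <- "date"
    df$date_value[idx_date[ok]] <- parsed[ok]
    # unparseable date-like strings degrade to word tokens
  }

  # expand a/b pairs (e.g. blood pressure 120/80) into two number tokens
  df$pair_id <- NA_integer_
  idx_pair <- which(is_pair & df$kind == "word")
  if (length(idx_pair) > 0) {
    df$.row <- seq_len(nrow(df))
    pair_rows <- df[idx_pair, ]
    halves <- stringr::str_split_fixed(pair_rows$surface, "/", 2)
    first <- pair_rows %>%
      dplyr::mutate(surface = halves[, 1], kind = "number",
                    value = as.numeric(halves[, 1]),
                    pair_id = seq_along(idx_pair), .sub = 0)
    second <- pair_rows %>%
      dplyr::mutate(surface = halves[, 2], kind = "number",
                    value = as.numeric(halves[, 2]),
                    pair_id = seq_along(idx_pair), .sub = 1)
    df <- df[-idx_pair, ]
    df$.sub <- 0
    df <- dplyr::bind_rows(df, first, second) %>%
      dplyr::arrange(.data$.row, .data$.sub)
    df$.row <- NULL
    df$.sub <- NULL
  }

  df <- df %>%
    dplyr::group_by(.data$note_idx) %>%
    dplyr::mutate(
      position = dplyr::row_number() - 1L,
      sentence = cumsum(dplyr::lag(.data$surface %in% c(".", ";", "!"), default = FALSE)) + 1L
    ) %>%
    dplyr::ungroup()
  df[, c("note_idx", "position", "kind", "surface", "value", "date_value",
         "sentence", "pair_id")]
}

#' Tokenise a single note text
#'
#' Lower-cases the text and splits it into word, number, date and punctuation
#' tokens. Dates are recognised in `dd/mm/yyyy`, `dd.mm.yy` and `"12 jan
#' 2005"` dialects; `a/b` number pairs (e.g. blood pressure readings) are
#' split into two number tokens. Date-like strings that do not parse to a
#' valid calendar date degrade to word tokens.
#'
#' @param text A single character string.
#' @return A tibble with columns `position` (0-based), `kind` (word, number,
#'   date, punct), `surface`, `value` (for numbers), `date_value` (for
#'   dates), `sentence`, `pair_id` (shared by the two halves of an a/b pair).
#' @examples
#' tokenize("bp 120/80 mmhg")
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1)
  tokenize_corpus(text) %>% dplyr::select(-"note_idx")
}

# All strings obtainable from `word` by one letter insertion or one letter
# substitution.
edit1_neighbours <- function(word) {
  chars <- strsplit(word, "")[[1]]
  n <- length(chars)
  letters26 <- letters
  subs <- unlist(lapply(seq_len(n), function(i) {
    tmp <- vapply(letters26, function(l) {
      if (l == chars[i]) return(NA_character_)
      paste0(paste(chars[seq_len(i - 1)], collapse = ""), l,
             paste(chars[seq_len(n)[-seq_len(i)]], collapse = ""))
    }, character(1))
    tmp[!is.na(tmp)]
  }))
  ins <- unlist(lapply(0:n, function(i) {
    pre <- paste(chars[seq_len(i)], collapse = "")
    post <- if (i < n) paste(chars[(i + 1):n], collapse = "") else ""
    paste0(pre, letters26, post)
  }))
  unique(c(subs, ins))
}

#' Dictionary spelling correction at edit distance one
#'
#' For each word not found in either lexicon, enumerates all single-letter
#' insertion and substitution neighbours and returns the best lexicon word
#' among them, preferring medical words over non-medical ones, then words
#' occurring in more terminology terms, then the lexicographically smallest.
#' Words already in a lexicon, or shorter than the configured minimum length
#' (abbreviations), are returned unchanged; words with no neighbour in either
#' lexicon are returned unchanged too.
#'
#' @param word Character vector of lower-case words.
#' @param resources A `notecoder_resources` list.
#' @return Character vector: the corrected word, or the input where no
#'   correction applies.
#' @examples
#' res <- default_resources()
#' correct_spelling("chst", res)
#' @export
correct_spelling <- function(word, resources) {
  cfg <- resources$config
  known <- word %in% resources$medical_words | word %in% resources$nonmedical_words
  todo <- unique(word[!known & nchar(word) >= cfg$min_correct_len &
                        stringr::str_detect(word, "^[a-z]+$")])
  if (length(todo) == 0) return(word)
  fixes <- vapply(todo, function(w) {
    nb <- edit1_neighbours(w)
    med <- nb[nb %in% resources$medical_words]
    if (length(med) > 0) {
      freq <- as.integer(resources$word_freq[med])
      med <- med[order(-freq, med)]
      return(med[1])
    }
    nonmed <- sort(nb[nb %in% resources$nonmedical_words])
    if (length(nonmed) > 0) return(nonmed[1])
    w
  }, character(1))
  out <- word
  hit <- match(word, todo)
  out[!is.na(hit)] <- fixes[hit[!is.na(hit)]]
  out
}

#' Default contextual attribute rules
#'
#' The ordered cue rules applied to token sequences: negation cues mark the
#' following concept absent, suspicion cues mark it suspected, history cues
#' mark it part of the medical history. Rules are applied sequentially with
#' precedence absent > suspected > history; the default attribute is
#' `current_or_previous`.
#'
#' @return A tibble with columns `order`, `attribute`, `cues` (regular
#'   expression over token surfaces).
#' @export
default_attribute_rules <- function() {
  tibble::tibble(
    order = 1:3,
    attribute = c("absent", "suspected", "history"),
    cues = c("^(no|not|denies|nil|without)$",
             "^(\\?|possible|suspected|query|likely|probable)$",
             "^(previous|h/o)$")
  )
}

word_numbers <- c(a = 1, one = 1, two = 2, three = 3, four = 4, five = 5,
                  six = 6, seven = 7, eight = 8, nine = 9, ten = 10)

# Detect "[n] year(s) ago" in a sentence's tokens; returns n in years or NA.
years_ago_n <- function(surfaces, values) {
  idx <- which(surfaces %in% c("year", "years", "yr", "yrs"))
  for (i in idx) {
    if (i + 1 <= length(surfaces) && surfaces[i + 1] == "ago" && i >= 2) {
      prev <- surfaces[i - 1]
      if (!is.na(values[i - 1])) return(values[i - 1])
      if (prev %in% names(word_numbers)) return(unname(word_numbers[prev]))
    }
  }
  NA_real_
}

validate_attribute_rules <- function(rules) {
  stopifnot(all(c("order", "attribute", "cues") %in% names(rules)))
  for (i in seq_len(nrow(rules))) {
    ok <- tryCatch({ stringr::str_detect("x", rules$cues[i]); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("malformed attribute rule pattern at rule ", i, ": ", rules$cues[i])
    if (!rules$attribute[i] %in% c("absent", "suspected", "history")) {
      stop("unknown attribute in rule ", i, ": ", rules$attribute[i])
    }
  }
  rules[order(rules$order), ]
}

#' Assign contextual attributes to tokens
#'
#' Applies the ordered cue rules to a tokenised note. A cue governs the
#' tokens that follow it in the same sentence, up to the configured scope
#' limit or an adversative terminator ("but", "however"). When several cues
#' govern a token, precedence is absent > suspected > history (rule order).
#' The bigram "history of" and the relative-date pattern "[n] year(s) ago"
#' also set the history attribute; the latter marks the whole sentence and
#' records an inferred event offset of n * 365 days.
#'
#' @param tokens A token tibble from [tokenize()] (a `note_idx` column is
#'   added if absent).
#' @param rules Attribute rule tibble, see [default_attribute_rules()].
#' @param scope Maximum number of tokens a cue governs.
#' @return `tokens` with columns `attribute` and `hist_years` (years-ago
#'   offset for history sentences, NA otherwise) added.
#' @examples
#' apply_attribute_rules(tokenize("no chest pain"))
#' @export
apply_attribute_rules <- function(tokens, rules = default_attribute_rules(),
                                  scope = 6L) {
  rules <- validate_attribute_rules(rules)
  if (!"note_idx" %in% names(tokens)) tokens$note_idx <- 1L
  tokens$attribute <- "current_or_previous"
  tokens$hist_years <- NA_real_
  if (nrow(tokens) == 0) return(tokens)

  cue_any <- rep(FALSE, nrow(tokens))
  for (i in seq_len(nrow(rules))) {
    cue_any <- cue_any | stringr::str_detect(tokens$surface, rules$cues[i])
  }
  hist_of <- tokens$surface == "history" &
    dplyr::lead(tokens$surface, default = "") == "of"
  ago_tok <- tokens$surface == "ago"
  need <- tokens$note_idx %in% tokens$note_idx[cue_any | hist_of | ago_tok]
  if (!any(need)) return(tokens)

  key <- paste(tokens$note_idx, tokens$sentence)
  for (k in unique(key[need])) {
    sel <- which(key == k)
    surf <- tokens$surface[sel]
    vals <- tokens$value[sel]
    m <- length(sel)
    attr_s <- rep("current_or_previous", m)

    n_ago <- years_ago_n(surf, vals)
    if (!is.na(n_ago)) {
      attr_s[] <- "history"
      tokens$hist_years[sel] <- n_ago
    }
    term_pos <- which(surf %in% c("but", "however"))
    # lowest rule order wins, so apply rules in reverse precedence
    for (i in rev(seq_len(nrow(rules)))) {
      cue_pos <- which(stringr::str_detect(surf, rules$cues[i]))
      if (rules$attribute[i] == "history") {
        cue_pos <- c(cue_pos, which(surf == "history" & dplyr::lead(surf, default = "") == "of"))
      }
      for (cp in cue_pos) {
        lim <- cp + scope
        stop_at <- term_pos[term_pos > cp]
        if (length(stop_at) > 0) lim <- min(lim, min(stop_at) - 1L)
        span <- seq(cp + 1L, min(lim, m))
        if (length(span) > 0 && span[1] <= m) attr_s[span] <- rules$attribute[i]
      }
    }
    tokens$attribute[sel] <- attr_s
  }
  tokens
}

#' Score a match candidate
#'
#' The declared linear scoring function: coverage of the matched term's words
#' minus penalties for synonym substitutions and spelling corrections,
#' clipped to \[0, 1\]:
#' `score = w_cov * n_matched / n_term_words - w_syn * substitutions -
#' w_sp * corrections`.
#' An exact full-coverage match with no substitutions or corrections scores
#' 1. The score is monotone non-increasing in substitutions and corrections.
#'
#' @param candidates A tibble with columns `n_matched`, `n_term_words`,
#'   `substitutions_used`, `corrections_used`.
#' @param config An [engine_config()] list.
#' @return `candidates` with a `score` column added.
#' @examples
#' score_candidate(tibble::tibble(n_matched = 3, n_term_words = 3,
#'                                substitutions_used = 1, corrections_used = 0))
#' @export
score_candidate <- function(candidates, config = engine_config()) {
  s <- config$w_cov * candidates$n_matched / candidates$n_term_words -
    config$w_syn * candidates$substitutions_used -
    config$w_sp * candidates$corrections_used
  candidates$score <- pmin(1, pmax(0, s))
  candidates
}

# Apply synonym rules to a vector of phrases; returns tibble(.id, phrase, n_subs)
# for phrases changed by one rule application (first occurrence, word-bounded).
apply_synonyms_once <- function(phrases, synonyms) {
  out <- list()
  for (i in seq_len(nrow(synonyms))) {
    pat <- paste0("\\b", stringr::str_replace_all(synonyms$source[i],
                                                  "([.?*+^$()\\[\\]{}|\\\\])", "\\\\\\1"),
                  "\\b")
    repl <- synonyms$target[i]
    new <- stringr::str_replace(phrases, pat, repl)
    changed <- which(new != phrases)
    if (length(changed) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(.id = changed, phrase = new[changed])
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(.id = integer(0), phrase = character(0)))
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

#' Generate term-match candidates for annotated tokens
#'
#' Considers every n-gram of 1 to `max_span` consecutive word tokens
#' (spelling-corrected surfaces), matching each against the terminology: an
#' exact phrase match, a match against the head words of a longer term
#' (reduced coverage), or a match after up to `max_substitutions` synonym
#' substitutions. Each candidate records its token span, the substitutions
#' and corrections used, and its score.
#'
#' @param tokens Attribute-annotated token tibble (see
#'   [apply_attribute_rules()]); a `corrected` column is used if present.
#' @param resources A `notecoder_resources` list.
#' @return A candidate tibble with columns `note_idx`, `sentence`,
#'   `start_pos`, `end_pos`, `span_len`, `code`, `n_matched`, `n_term_words`,
#'   `substitutions_used`, `corrections_used`, `attribute`, `cert_line`,
#'   `score`.
#' @export
generate_candidates <- function(tokens, resources) {
  cfg <- resources$config
  if (!"note_idx" %in% names(tokens)) tokens$note_idx <- 1L
  if (!"corrected" %in% names(tokens)) tokens$corrected <- tokens$surface
  if (!"attribute" %in% names(tokens)) tokens$attribute <- "current_or_previous"
  empty <- tibble::tibble(
    note_idx = integer(0), sentence = integer(0), start_pos = integer(0),
    end_pos = integer(0), span_len = integer(0), code = character(0),
    n_matched = integer(0), n_term_words = integer(0),
    substitutions_used = integer(0), corrections_used = integer(0),
    attribute = character(0), cert_line = character(0), score = numeric(0)
  )
  words <- tokens %>%
    dplyr::filter(.data$kind == "word",
                  !.data$surface %in% c("1a", "1b", "1c", "ii")) %>%
    dplyr::group_by(.data$note_idx) %>%
    dplyr::mutate(run = cumsum(c(1L, diff(.data$position)) != 1L)) %>%
    dplyr::ungroup()
  if (nrow(words) == 0) return(empty)

  words <- words %>%
    dplyr::group_by(.data$note_idx, .data$run) %>%
    dplyr::mutate(widx = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(was_corrected = .data$corrected != .data$surface)

  spans <- purrr::map_dfr(seq_len(cfg$max_span), function(n) {
    words %>%
      dplyr::group_by(.data$note_idx, .data$run) %>%
      dplyr::mutate(
        end_pos = dplyr::lead(.data$position, n - 1L),
        phrase = if (n == 1) .data$corrected else {
          parts <- purrr::map(seq_len(n) - 1L, ~ dplyr::lead(corrected, .x))
          do.call(paste, parts)
        },
        n_corr = if (n == 1) as.integer(.data$was_corrected) else {
          Reduce(`+`, purrr::map(seq_len(n) - 1L,
                                 ~ as.integer(dplyr::lead(was_corrected, .x, default = FALSE))))
        }
      ) %>%
      dplyr::ungroup() %>%
      dplyr::filter(!is.na(.data$end_pos)) %>%
      dplyr::transmute(
        note_idx = .data$note_idx, sentence = .data$sentence,
        start_pos = .data$position, end_pos = .data$end_pos,
        span_len = n, phrase = .data$phrase,
        corrections_used = .data$n_corr
      )
  })
  if (nrow(spans) == 0) return(empty)
  spans$.id <- seq_len(nrow(spans))

  variants <- dplyr::mutate(spans[, c(".id", "phrase")], substitutions_used = 0L)
  if (cfg$max_substitutions >= 1 && nrow(resources$synonyms) > 0) {
    v1 <- apply_synonyms_once(spans$phrase, resources$synonyms)
    if (nrow(v1) > 0) {
      v1$substitutions_used <- 1L
      variants <- dplyr::bind_rows(variants, v1)
      if (cfg$max_substitutions >= 2) {
        v2 <- apply_synonyms_once(v1$phrase, resources$synonyms)
        if (nrow(v2) > 0) {
          v2$.id <- v1$.id[v2$.id]
          v2$substitutions_used <- 2L
          variants <- dplyr::bind_rows(variants, dplyr::distinct(v2))
        }
      }
    }
  }

  hits <- dplyr::inner_join(variants, resources$phrase_index, by = "phrase",
                            relationship = "many-to-many")
  if (nrow(hits) == 0) return(empty)
  hits <- hits %>%
    dplyr::group_by(.data$.id, .data$code) %>%
    dplyr::slice_min(.data$substitutions_used, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()

  cand <- dplyr::inner_join(
    spans[, c(".id", "note_idx", "sentence", "start_pos", "end_pos",
              "span_len", "corrections_used")],
    hits[, c(".id", "code", "n_matched", "n_term_words", "substitutions_used")],
    by = ".id"
  )
  cand$.id <- NULL

  # attribute at span start; certificate line marker immediately before span
  tok_key <- paste(tokens$note_idx, tokens$position)
  start_match <- match(paste(cand$note_idx, cand$start_pos), tok_key)
  cand$attribute <- tokens$attribute[start_match]
  before <- match(paste(cand$note_idx, cand$start_pos - 1L), tok_key)
  marker <- ifelse(is.na(before), NA_character_, tokens$surface[before])
  cand$cert_line <- dplyr::case_when(
    marker %in% c("1a", "1b", "1c") ~ marker,
    marker == "ii" ~ "2",
    TRUE ~ NA_character_
  )
  score_candidate(cand, cfg)
}

# Greedy overlap resolution: longest span, then highest score, then fewest
# substitutions, then lowest code. Returns the selected candidate rows.
resolve_overlaps <- function(cand) {
  if (nrow(cand) <= 1) return(cand)
  cand <- cand %>%
    dplyr::arrange(.data$note_idx, -.data$span_len, -.data$score,
                   .data$substitutions_used, .data$code)
  keep <- logical(nrow(cand))
  taken <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cand))) {
    span_keys <- paste(cand$note_idx[i], seq(cand$start_pos[i], cand$end_pos[i]))
    if (!any(vapply(span_keys, function(kk) !is.null(taken[[kk]]), logical(1)))) {
      keep[i] <- TRUE
      for (kk in span_keys) taken[[kk]] <- TRUE
    }
  }
  cand[keep, ]
}

#' Bind quantitative results to measurable concepts
#'
#' For each selected match of a measurable concept (pulse, blood pressure,
#' laboratory counts, ...), binds the nearest unclaimed number token within
#' the configured window in the same sentence, preferring numbers that follow
#' the concept. The two halves of an a/b pair (blood pressure) become
#' `numeric_value` and `numeric_value2`. A unit word immediately after the
#' number is kept when it belongs to the closed unit vocabulary. Numbers
#' adjacent to no measurable concept are never emitted. Numbers are bound
#' only to spans with the `current_or_previous` attribute.
#'
#' @param tokens Token tibble for the same notes.
#' @param matches Selected candidate tibble (see [generate_candidates()]).
#' @param resources A `notecoder_resources` list.
#' @return `matches` with `numeric_value`, `numeric_value2` and `unit`
#'   columns added.
#' @export
extract_numeric_results <- function(tokens, matches, resources) {
  cfg <- resources$config
  matches$numeric_value <- NA_real_
  matches$numeric_value2 <- NA_real_
  matches$unit <- NA_character_
  if (nrow(matches) == 0) return(matches)
  if (!"note_idx" %in% names(tokens)) tokens$note_idx <- 1L

  nums <- tokens %>%
    dplyr::filter(.data$kind == "number") %>%
    dplyr::mutate(claimed = FALSE)
  if (nrow(nums) == 0) return(matches)

  meas_idx <- which(matches$code %in% cfg$measurable_codes &
                      matches$attribute == "current_or_previous")
  tok_key <- paste(tokens$note_idx, tokens$position)
  for (i in meas_idx) {
    cand_n <- which(nums$note_idx == matches$note_idx[i] &
                      nums$sentence == matches$sentence[i] & !nums$claimed)
    if (length(cand_n) == 0) next
    after <- nums$position[cand_n] - matches$end_pos[i]
    before <- matches$start_pos[i] - nums$position[cand_n]
    dist <- ifelse(after > 0, after, ifelse(before > 0, before, NA))
    prefer <- ifelse(after > 0, 0, 1)  # prefer following numbers on ties
    ok <- which(!is.na(dist) & dist <= cfg$numeric_window)
    if (length(ok) == 0) next
    j <- cand_n[ok[order(dist[ok], prefer[ok])][1]]
    matches$numeric_value[i] <- nums$value[j]
    nums$claimed[j] <- TRUE
    unit_after <- j
    if (!is.na(nums$pair_id[j])) {
      partner <- which(nums$note_idx == nums$note_idx[j] &
                         nums$pair_id == nums$pair_id[j] &
                         nums$position != nums$position[j])
      if (length(partner) == 1) {
        matches$numeric_value2[i] <- nums$value[partner]
        nums$claimed[partner] <- TRUE
        unit_after <- partner
      }
    }
    nxt <- match(paste(nums$note_idx[unit_after], nums$position[unit_after] + 1L), tok_key)
    if (!is.na(nxt) && tokens$kind[nxt] == "word" &&
        tokens$surface[nxt] %in% cfg$unit_vocabulary) {
      matches$unit[i] <- tokens$surface[nxt]
    }
  }
  matches
}

#' Code a batch of notes
#'
#' The full pipeline: clean, tokenise, spell-correct, attribute detection,
#' candidate generation, scoring, overlap resolution and numeric binding.
#' Overlapping candidates are resolved by longest span, then highest score,
#' then fewest substitutions, then lowest code; only candidates scoring at
#' least the configured threshold are emitted. The output contains only
#' codes, attributes, numbers, dates and closed-vocabulary units - never any
#' fragment of the input text.
#'
#' @param notes A tibble with columns `patient_id`, `note_date` (Date or
#'   ISO-8601 string), `text`.
#' @param resources A `notecoder_resources` list.
#' @return A tibble with one row per extracted fact: `patient_id`,
#'   `note_date`, `event_date`, `code`, `attribute`, `numeric_value`,
#'   `numeric_value2`, `unit`, `score`, `cert_line`, `note_idx`, `start_pos`,
#'   `end_pos`.
#' @examples
#' res <- default_resources()
#' notes <- tibble::tibble(patient_id = "p1", note_date = as.Date("2005-06-01"),
#'                         text = "no chest pain. ?uti. bp 120/80")
#' link_notes(notes, res)
#' @export
link_notes <- function(notes, resources) {
  stopifnot(all(c("patient_id", "note_date", "text") %in% names(notes)))
  cfg <- resources$config
  out_cols <- c("patient_id", "note_date", "event_date", "code", "attribute",
                "numeric_value", "numeric_value2", "unit", "score",
                "cert_line", "note_idx", "start_pos", "end_pos")
  empty <- tibble::tibble(
    patient_id = character(0), note_date = as.Date(character(0)),
    event_date = as.Date(character(0)), code = character(0),
    attribute = character(0), numeric_value = numeric(0),
    numeric_value2 = numeric(0), unit = character(0), score = numeric(0),
    cert_line = character(0), note_idx = integer(0), start_pos = integer(0),
    end_pos = integer(0)
  )
  if (nrow(notes) == 0) return(empty)
  notes$note_date <- as.Date(notes$note_date)

  cleaned <- clean_text(notes$text, resources$cleanup_rules)
  tokens <- tokenize_corpus(cleaned)
  if (nrow(tokens) == 0) return(empty)

  tokens$corrected <- tokens$surface
  wsel <- tokens$kind == "word"
  tokens$corrected[wsel] <- correct_spelling(tokens$surface[wsel], resources)
  tokens <- apply_attribute_rules(tokens, scope = cfg$negation_scope)

  cand <- generate_candidates(tokens, resources)
  cand <- cand[cand$score >= cfg$threshold, ]
  if (nrow(cand) == 0) return(empty)
  sel <- resolve_overlaps(cand) %>%
    dplyr::arrange(.data$note_idx, .data$start_pos)
  sel <- extract_numeric_results(tokens, sel, resources)

  sel$patient_id <- notes$patient_id[sel$note_idx]
  sel$note_date <- notes$note_date[sel$note_idx]

  # event date: note date, unless the span is history-attributed and the
  # sentence carries a relative date ("[n] years ago") or a date token
  sel$event_date <- sel$note_date
  hist <- which(sel$attribute == "history")
  if (length(hist) > 0) {
    sent_key <- paste(tokens$note_idx, tokens$sentence)
    for (i in hist) {
      k <- paste(sel$note_idx[i], sel$sentence[i])
      stoks <- tokens[sent_key == k, ]
      yrs <- stoks$hist_years[!is.na(stoks$hist_years)]
      if (length(yrs) > 0) {
        sel$event_date[i] <- sel$note_date[i] - round(yrs[1] * 365)
      } else {
        dts <- stoks$date_value[stoks$kind == "date" & stoks$attribute == "history"]
        dts <- dts[!is.na(dts)]
        if (length(dts) > 0) sel$event_date[i] <- dts[1]
      }
    }
  }
  sel <- sel %>%
    dplyr::arrange(.data$note_idx, .data$start_pos)
  sel[, out_cols]
}

#' Code a single note
#'
#' Convenience wrapper around [link_notes()] for one note.
#'
#' @param patient_id Patient identifier.
#' @param note_date Note date.
#' @param text Note text.
#' @param resources A `notecoder_resources` list.
#' @return See [link_notes()].
#' @export
link_note <- function(patient_id, note_date, text, resources) {
  link_notes(tibble::tibble(patient_id = patient_id,
                            note_date = as.Date(note_date), text = text),
             resources)
}

#' Verify that engine output contains only coded or numeric data
#'
#' The safety contract of the engine: every emitted code must exist in the
#' terminology, every unit must come from the closed unit vocabulary, the
#' attribute and certificate-line fields must take enumerated values, and the
#' numeric fields must be numeric. Violations are listed per record.
#'
#' @param outputs A coded-output tibble (see [link_notes()]).
#' @param resources A `notecoder_resources` list.
#' @return A list with `pass` (logical) and `violations` (tibble with `row`
#'   and `reason`).
#' @export
verify_coded_only <- function(outputs, resources) {
  cfg <- resources$config
  v <- list()
  add <- function(rows, reason) {
    if (length(rows) > 0) {
      v[[length(v) + 1]] <<- tibble::tibble(row = rows, reason = reason)
    }
  }
  if (nrow(outputs) > 0) {
    add(which(!outputs$code %in% resources$terminology$code),
        "code not in terminology")
    if ("unit" %in% names(outputs)) {
      add(which(!is.na(outputs$unit) & !outputs$unit %in% cfg$unit_vocabulary),
          "unit not in closed vocabulary")
    }
    if ("attribute" %in% names(outputs)) {
      add(which(!outputs$attribute %in%
                  c("current_or_previous", "absent", "suspected", "history")),
          "attribute not in enumeration")
    }
    if ("cert_line" %in% names(outputs)) {
      add(which(!is.na(outputs$cert_line) &
                  !outputs$cert_line %in% c("1a", "1b", "1c", "2")),
          "certificate line not in enumeration")
    }
    for (col in c("numeric_value", "numeric_value2", "score")) {
      if (col %in% names(outputs) && !is.numeric(outputs[[col]])) {
        add(seq_len(nrow(outputs)), paste0(col, " is not numeric"))
      }
    }
  }
  violations <- if (length(v) > 0) dplyr::bind_rows(v) else
    tibble::tibble(row = integer(0), reason = character(0))
  list(pass = nrow(violations) == 0, violations = violations)
}
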