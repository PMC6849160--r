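test_that("cleanup removes literal boilerplate phrases and is idempotent", {
  rule <- "scanned document: letter from hospital."
  expect_equal(clean_text("Scanned document: Letter from hospital. chest pain settled", rule),
               "chest pain settled")
  expect_equal(clean_text("chest pain settled", rule), "chest pain settled")
  expect_equal(clean_text("scanned document: letter from hospital.", rule), "")
  expect_equal(clean_text("", rule), "")
  txts <- c("end of report. bp 120/80", "no change", "")
  rules <- test_res()$cleanup_rules
  once <- clean_text(txts, rules)
  expect_identical(clean_text(once, rules), once)
})

test_that("tokeniser classifies words, numbers, pairs and dates", {
  t1 <- tokenize("BP 120/80")
  expect_equal(t1$kind, c("word", "number", "number"))
  expect_equal(t1$surface[1], "bp")
  expect_equal(t1$value[-1], c(120, 80))
  expect_equal(t1$pair_id[2], t1$pair_id[3])

  expect_equal(nrow(tokenize("")), 0)

  t2 <- tokenize("pulse 88.5 today")
  expect_equal(t2$value[2], 88.5)

  # invalid dates degrade to word tokens
  t3 <- tokenize("seen 40/20/2004")
  expect_equal(t3$kind, c("word", "word"))

  # newline is always a sentence boundary
  t4 <- tokenize("chest pain\nno oedema")
  expect_equal(unique(t4$sentence[t4$surface %in% c("chest", "pain")]), 1L)
  expect_equal(unique(t4$sentence[t4$surface %in% c("no", "oedema")]), 2L)
})

test_that("date recognition agrees with an independent parser over a grid of dates", {
  days <- seq(as.Date("2003-01-15"), as.Date("2004-12-15"), by = "37 days")
  for (d in as.list(days)) {
    for (fmt in c("%d/%m/%Y", "%d.%m.%y")) {
      tok <- tokenize(paste("mi", format(d, fmt)))
      expect_equal(tok$kind[2], "date", info = format(d, fmt))
      expect_equal(tok$date_value[2], d, info = fmt)
    }
    tok <- tokenize(paste("mi", tolower(format(d, "%d %b %Y"))))
    expect_equal(tok$date_value[2], d)
  }
})

test_that("spelling correction returns only edit-distance-one lexicon words", {
  res <- test_res()
  expect_equal(correct_spelling("chst", res), "chest")    # one insertion
  expect_equal(correct_spelling("angima", res), "angina") # one substitution
  expect_equal(correct_spelling("xqzt", res), "xqzt")     # no neighbour
  expect_equal(correct_spelling("mi", res), "mi")         # too short: abbreviation
  expect_equal(correct_spelling("chest", res), "chest")   # already known

  # contract: every correction is reachable by exactly one insertion or
  # substitution (brute-force neighbour enumeration)
  probes <- c("chst", "angima", "pneumnia", "strke", "oedma", "diabtes",
              "asthna", "vomitin", "puls", "failre")
  for (w in probes) {
    fixed <- correct_spelling(w, res)
    if (fixed != w) {
      nb <- notecoder:::edit1_neighbours(w)
      expect_true(fixed %in% nb, info = w)
      expect_true(fixed %in% c(res$medical_words, res$nonmedical_words), info = w)
    }
  }
})

test_that("correction preference is medical first, then term frequency, then lexicographic", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("code\tterm",
               "182..00\tpain",
               "199..00\tpain scale",
               "242..00\tmain artery",
               "246..00\tgain",
               "173..00\tchest",
               "2C2..11\tvest"),
             file.path(dir, "t.tsv"))
  writeLines(c("source\ttarget", "x\ty"), file.path(dir, "s.tsv"))
  writeLines("best", file.path(dir, "l.tsv"))
  res <- load_terminology(file.path(dir, "t.tsv"), file.path(dir, "s.tsv"),
                          file.path(dir, "l.tsv"))
  # "aain" has medical neighbours pain (freq 2), main (1), gain (1)
  expect_equal(correct_spelling("aain", res), "pain")
  # "zest": medical neighbour "vest" beats non-medical "best"
  expect_equal(correct_spelling("zest", res), "vest")
  # "cest": medical neighbours chest (insertion) and vest (substitution),
  # equal frequency -> lexicographically smallest
  expect_equal(correct_spelling("cest", res), "chest")
})

test_that("attribute cues set absent, suspected and history with correct scope", {
  res <- test_res()
  out <- link_note("p", "2005-01-01", "no chest pain", res)
  expect_equal(out$code, "182..00")
  expect_equal(out$attribute, "absent")

  out <- link_note("p", "2005-01-01", "?uti", res)
  expect_equal(out$code, "K190.00")
  expect_equal(out$attribute, "suspected")

  out <- link_note("p", "2005-01-01", "chest pain", res)
  expect_equal(out$attribute, "current_or_previous")

  out <- link_note("p", "2005-01-01", "h/o angina pectoris", res)
  expect_equal(out$attribute, "history")

  # adversative conjunction terminates the cue's scope
  out <- link_note("p", "2005-01-01", "no oedema but chest pain", res)
  expect_equal(out$attribute[out$code == "R023.00"], "absent")
  expect_equal(out$attribute[out$code == "182..00"], "current_or_previous")

  # sentence boundary terminates the scope
  out <- link_note("p", "2005-01-01", "no oedema. chest pain", res)
  expect_equal(out$attribute[out$code == "182..00"], "current_or_previous")

  # precedence when cues conflict: absent > suspected
  out <- link_note("p", "2005-01-01", "no possible pneumonia", res)
  expect_equal(out$attribute, "absent")

  # cue scope is capped at the configured token limit
  toks <- apply_attribute_rules(tokenize("no a b c d e f chest pain"), scope = 6L)
  expect_equal(toks$attribute[toks$surface == "chest"], "current_or_previous")
})

test_that("malformed attribute rule patterns fail at load, not at apply time", {
  bad <- tibble::tibble(order = 1L, attribute = "absent", cues = "([")
  expect_error(apply_attribute_rules(tokenize("chest pain"), bad), "malformed attribute rule")
  unk <- tibble::tibble(order = 1L, attribute = "maybe", cues = "^no$")
  expect_error(apply_attribute_rules(tokenize("chest pain"), unk), "unknown attribute")
})

test_that("candidate generation covers exact, prefix, and synonym-substituted matches", {
  res <- test_res()
  toks <- apply_attribute_rules(tokenize("acute myocardial infarction"))
  cand <- generate_candidates(toks, res)
  # prefix match against the 4-word term scores 3/4 on the full span
  # (shorter head spans also match at proportionally lower coverage)
  g30z <- cand[cand$code == "G30z.00" & cand$span_len == 3, ]
  expect_equal(nrow(g30z), 1)
  expect_equal(g30z$n_matched, 3L)
  expect_equal(g30z$n_term_words, 4L)
  expect_equal(g30z$score, 0.75)

  toks <- apply_attribute_rules(tokenize("heart attack"))
  cand <- generate_candidates(toks, res)
  mi <- cand[cand$code == "G30..00", ]
  expect_equal(mi$substitutions_used, 1L)
  expect_equal(mi$score, 0.85)

  toks <- apply_attribute_rules(tokenize("the patient walked"))
  cand <- generate_candidates(toks, res)
  expect_equal(nrow(cand[cand$score >= 0.7, ]), 0)

  expect_equal(nrow(generate_candidates(tokenize(""), res)), 0)
})

test_that("the declared scoring formula evaluates as specified", {
  sc <- function(m, t, s, k) {
    score_candidate(tibble::tibble(n_matched = m, n_term_words = t,
                                   substitutions_used = s,
                                   corrections_used = k))$score
  }
  expect_equal(sc(3, 3, 0, 0), 1.0)   # exact full match
  expect_equal(sc(3, 3, 1, 0), 0.85)  # one synonym substitution
  expect_equal(sc(2, 4, 0, 0), 0.5)   # half coverage before penalties
  expect_equal(sc(4, 4, 0, 1), 0.9)   # one spelling correction
  expect_equal(sc(1, 5, 2, 2), 0)     # clipped at zero
})

test_that("score is monotone non-increasing in substitutions and corrections", {
  grid <- expand.grid(m = 1:5, t = 1:5, s = 0:2, k = 0:2)
  grid <- grid[grid$m <= grid$t, ]
  base <- score_candidate(tibble::tibble(
    n_matched = grid$m, n_term_words = grid$t,
    substitutions_used = grid$s, corrections_used = grid$k))$score
  more_subs <- score_candidate(tibble::tibble(
    n_matched = grid$m, n_term_words = grid$t,
    substitutions_used = grid$s + 1L, corrections_used = grid$k))$score
  more_corr <- score_candidate(tibble::tibble(
    n_matched = grid$m, n_term_words = grid$t,
    substitutions_used = grid$s, corrections_used = grid$k + 1L))$score
  expect_true(all(more_subs <= base))
  expect_true(all(more_corr <= base))
})

test_that("the full pipeline codes a mixed note and misspellings end to end", {
  res <- test_res()
  out <- link_note("p1", "2005-06-01", "no chest pain. ?uti. bp 120/80", res)
  expect_equal(nrow(out), 3)
  expect_equal(out$code, c("182..00", "K190.00", "246..00"))
  expect_equal(out$attribute, c("absent", "suspected", "current_or_previous"))
  expect_equal(out$numeric_value[3], 120)
  expect_equal(out$numeric_value2[3], 80)

  out <- link_note("p1", "2005-06-01", "chst pain", res)
  expect_equal(out$code, "182..00")
  expect_equal(out$attribute, "current_or_previous")
  expect_equal(out$score, 0.9)

  expect_equal(nrow(link_note("p1", "2005-06-01", "", res)), 0)
})

test_that("relative dates shift the event date for history spans", {
  res <- test_res()
  out <- link_note("p", "2005-06-01", "mi one year ago", res)
  expect_equal(out$attribute, "history")
  expect_equal(out$event_date, as.Date("2005-06-01") - 365)

  out <- link_note("p", "2005-06-01", "previous stroke 12/03/2004", res)
  expect_equal(out$attribute, "history")
  expect_equal(out$event_date, as.Date("2004-03-12"))

  out <- link_note("p", "2005-06-01", "chest pain", res)
  expect_equal(out$event_date, as.Date("2005-06-01"))
})

test_that("numeric results bind to adjacent measurable concepts only", {
  res <- test_res()
  out <- link_note("p", "2005-01-01", "pulse 88", res)
  expect_equal(out$code, "242..00")
  expect_equal(out$numeric_value, 88)

  out <- link_note("p", "2005-01-01", "bp 120/80 mmhg", res)
  expect_equal(out$numeric_value, 120)
  expect_equal(out$numeric_value2, 80)
  expect_equal(out$unit, "mmhg")

  # number before the concept still binds; non-measurable concept does not
  out <- link_note("p", "2005-01-01", "88 pulse chest pain", res)
  pulse <- out[out$code == "242..00", ]
  cp <- out[out$code == "182..00", ]
  expect_equal(pulse$numeric_value, 88)
  expect_true(is.na(cp$numeric_value))

  # an unattached number is never emitted as output
  out <- link_note("p", "2005-01-01", "score 99 noted", res)
  expect_false(99 %in% out$numeric_value)

  # negated measurables take no value
  out <- link_note("p", "2005-01-01", "no pulse 88", res)
  expect_true(is.na(out$numeric_value[out$code == "242..00"]))
})

test_that("overlapping candidates resolve to the longest span", {
  res <- test_res()
  out <- link_note("p", "2005-01-01", "irregular pulse", res)
  expect_equal(out$code, "2432.00")  # never the contained "pulse" span
  out <- link_note("p", "2005-01-01", "congestive heart failure", res)
  expect_equal(out$code, "G580.00")  # never the contained "heart failure"
  out <- link_note("p", "2005-01-01", "chest pain", res)
  expect_false("1M...00" %in% out$code)  # "pain" is contained
})

test_that("tie-broken duplicate terms resolve to the lowest code deterministically", {
  res <- test_res()
  # "chest pain" is the term of both 182..00 and R065.00
  out <- link_note("p", "2005-01-01", "chest pain", res)
  expect_equal(out$code, "182..00")
})

test_that("identical inputs produce byte-identical output files", {
  res <- test_res()
  corpus <- generate_notes(note_spec(n_notes = 60, seed = 7), res)
  f1 <- tempfile(); f2 <- tempfile()
  write_report(link_notes(corpus$notes, res), f1)
  write_report(link_notes(corpus$notes, res), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("coded-only verification accepts engine output and flags raw text", {
  res <- test_res()
  corpus <- generate_notes(note_spec(n_notes = 80, seed = 3), res)
  out <- link_notes(corpus$notes, res)
  chk <- verify_coded_only(out, res)
  expect_true(chk$pass)
  expect_equal(nrow(chk$violations), 0)

  bad <- out[1, ]
  bad$code <- "FREETEXT"
  chk <- verify_coded_only(dplyr::bind_rows(out, bad), res)
  expect_false(chk$pass)
  expect_equal(nrow(chk$violations), 1)

  expect_true(verify_coded_only(out[0, ], res)$pass)
})
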