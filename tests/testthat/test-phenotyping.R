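mk_events <- function(...) {
  rows <- list(...)
  df <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(patient_id = r[[1]], event_date = as.Date(r[[2]]),
                   code = r[[3]], source = r[[4]],
                   attribute = if (length(r) > 4) r[[5]] else "current_or_previous")
  }))
  combine_events(df)
}

one_case <- tibble::tibble(patient_id = "p1", mi_date = as.Date("2005-03-01"))

test_that("structured subtype records take precedence over earlier free text", {
  ev <- mk_events(list("p1", "2005-03-03", "G307100", "structured"),
                  list("p1", "2005-03-02", "G30X000", "freetext"))
  call <- classify_mi_subtype(ev, one_case)
  expect_equal(call$call, "NSTEMI")
  expect_equal(call$source_used, "structured")
})

test_that("free text is used when no structured subtype exists in window", {
  ev <- mk_events(list("p1", "2005-03-06", "G30X000", "freetext"))
  call <- classify_mi_subtype(ev, one_case)
  expect_equal(call$call, "STEMI")
  expect_equal(call$source_used, "freetext")
})

test_that("cases with no qualifying record are unclassified", {
  expect_equal(classify_mi_subtype(mk_events(list("p1", "2005-03-05", "182..00", "structured")),
                                   one_case)$call, "unclassified")
  # generic MI codes never produce a subtype call
  ev <- mk_events(list("p1", "2005-03-05", "G30z.00", "structured"))
  expect_equal(classify_mi_subtype(ev, one_case)$call, "unclassified")
  # records before the MI date never qualify
  ev <- mk_events(list("p1", "2005-02-25", "G30X.00", "structured"))
  expect_equal(classify_mi_subtype(ev, one_case)$call, "unclassified")
  # records outside the 30-day window never qualify
  ev <- mk_events(list("p1", "2005-04-05", "G30X.00", "structured"))
  expect_equal(classify_mi_subtype(ev, one_case)$call, "unclassified")
  # day-30 records do qualify; same-day records are distance zero
  ev <- mk_events(list("p1", "2005-03-31", "G30X.00", "structured"))
  expect_equal(classify_mi_subtype(ev, one_case)$call, "STEMI")
})

test_that("negated and suspected subtype mentions are ignored", {
  ev <- mk_events(list("p1", "2005-03-02", "G30X000", "freetext", "absent"),
                  list("p1", "2005-03-09", "G307111", "freetext", "suspected"))
  expect_equal(classify_mi_subtype(ev, one_case)$call, "unclassified")
})

test_that("within a source the closest record wins, ties by entry order", {
  ev <- mk_events(list("p1", "2005-03-10", "G30X.00", "structured"),
                  list("p1", "2005-03-04", "G307100", "structured"))
  expect_equal(classify_mi_subtype(ev, one_case)$call, "NSTEMI")
  # equidistant: first-entered record wins
  ev <- mk_events(list("p1", "2005-03-04", "G30X.00", "structured"),
                  list("p1", "2005-03-04", "G307100", "structured"))
  expect_equal(classify_mi_subtype(ev, one_case)$call, "STEMI")
})

test_that("confusion tabulation is exact, conserves marginals, and checks patients", {
  cases <- tibble::tibble(patient_id = paste0("p", 1:10),
                          mi_date = as.Date("2005-03-01"),
                          gold_subtype = "STEMI")
  calls <- tibble::tibble(patient_id = paste0("p", 1:10), call = "STEMI",
                          source_used = "structured",
                          record_date = as.Date("2005-03-02"))
  conf <- tabulate_subtype_confusion(calls, cases)
  expect_equal(notecoder:::confusion_cell(conf, "STEMI", "structured", "STEMI"), 10)
  expect_equal(sum(conf$n), 10)

  empty <- tabulate_subtype_confusion(calls[0, ], cases[0, ])
  expect_equal(sum(empty$n), 0)

  bad <- calls
  bad$patient_id[1] <- "zz"
  expect_error(tabulate_subtype_confusion(bad, cases), "unknown patient")
})

test_that("metrics are exact on a perfect confusion and undefined on empty calls", {
  cases <- tibble::tibble(patient_id = paste0("p", 1:20),
                          mi_date = as.Date("2005-03-01"),
                          gold_subtype = rep(c("STEMI", "NSTEMI"), each = 10))
  calls <- tibble::tibble(patient_id = cases$patient_id,
                          call = cases$gold_subtype,
                          source_used = "structured",
                          record_date = as.Date("2005-03-02"))
  conf <- tabulate_subtype_confusion(calls, cases)
  m <- subtype_metrics(conf, "structured_only")
  expect_true(all(m$point == 1))
  expect_equal(subtype_concordance(conf, "structured")$point, 1)
  expect_true(is.na(subtype_concordance(conf, "freetext")$point))

  none <- tibble::tibble(patient_id = cases$patient_id, call = "unclassified",
                         source_used = "none", record_date = as.Date(NA))
  conf0 <- tabulate_subtype_confusion(none, cases)
  m0 <- subtype_metrics(conf0, "structured_plus_freetext")
  expect_true(all(m0$point[m0$metric == "sensitivity"] == 0))
  expect_true(all(is.na(m0$point[m0$metric == "ppv"])))
})

test_that("combined-source sensitivity never falls below structured-only", {
  set.seed(31)
  for (rep in 1:20) {
    cases <- tibble::tibble(patient_id = paste0("p", 1:40),
                            mi_date = as.Date("2005-03-01"),
                            gold_subtype = sample(c("STEMI", "NSTEMI"), 40, TRUE))
    calls <- tibble::tibble(
      patient_id = cases$patient_id,
      source_used = sample(c("structured", "freetext", "none"), 40, TRUE,
                           prob = c(0.3, 0.2, 0.5))
    )
    calls$call <- ifelse(calls$source_used == "none", "unclassified",
                         sample(c("STEMI", "NSTEMI"), 40, TRUE))
    conf <- tabulate_subtype_confusion(calls, cases)
    m_s <- subtype_metrics(conf, "structured_only")
    m_b <- subtype_metrics(conf, "structured_plus_freetext")
    for (cl in c("STEMI", "NSTEMI")) {
      s1 <- m_s$point[m_s$class == cl & m_s$metric == "sensitivity"]
      s2 <- m_b$point[m_b$class == cl & m_b$metric == "sensitivity"]
      expect_gte(s2, s1)
    }
    # marginal conservation
    tot <- attr(conf, "gold_totals")
    expect_equal(sum(conf$n), sum(tot))
    for (g in names(tot)) expect_equal(sum(conf$n[conf$gold == g]), unname(tot[g]))
  }
})

test_that("tabulations agree with a per-patient brute-force recount on small cohorts", {
  res <- test_res()
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    cases <- tibble::tibble(patient_id = sprintf("q%03d", 1:n),
                            mi_date = as.Date("2005-01-01") + sample(0:200, n, TRUE),
                            gold_subtype = sample(c("STEMI", "NSTEMI"), n, TRUE))
    ev <- tibble::tibble(
      patient_id = sample(cases$patient_id, 3 * n, TRUE),
      code = sample(c("G30X.00", "G307100", "G30z.00", "182..00"), 3 * n, TRUE),
      source = sample(c("structured", "freetext"), 3 * n, TRUE),
      attribute = sample(c("current_or_previous", "absent"), 3 * n, TRUE,
                         prob = c(0.8, 0.2))
    )
    ev$event_date <- cases$mi_date[match(ev$patient_id, cases$patient_id)] +
      sample(-10:40, 3 * n, TRUE)
    combined <- combine_events(ev)
    calls <- classify_mi_subtype(combined, cases)

    # independent oracle: literal per-patient loop over the rule text
    cfg <- res$config
    for (i in seq_len(n)) {
      pe <- ev[ev$patient_id == cases$patient_id[i], ]
      pe <- pe[pe$code %in% c(cfg$stemi_codes, cfg$nstemi_codes) &
                 !pe$attribute %in% c("absent", "suspected") &
                 pe$event_date >= cases$mi_date[i] &
                 pe$event_date <= cases$mi_date[i] + 30, ]
      expected_call <- "unclassified"
      for (src in c("structured", "freetext")) {
        ps <- pe[pe$source == src, ]
        if (nrow(ps) > 0) {
          ps <- ps[order(ps$event_date - cases$mi_date[i]), ]
          expected_call <- ifelse(ps$code[1] %in% cfg$stemi_codes, "STEMI", "NSTEMI")
          break
        }
      }
      expect_equal(calls$call[calls$patient_id == cases$patient_id[i]],
                   expected_call, info = paste(rep, i))
    }
  }
})

test_that("symptom counts exclude negated/suspected mentions and handle edge counts", {
  cases <- tibble::tibble(patient_id = c("p1", "p2", "p3"),
                          mi_date = as.Date("2005-03-01"))
  ev <- mk_events(list("p1", "2005-02-27", "182..00", "structured"),
                  list("p2", "2005-02-27", "182..00", "freetext", "absent"),
                  list("p3", "2005-02-27", "182..00", "freetext", "suspected"))
  tab <- symptom_recording_table(ev, cases)
  cp <- tab[tab$item == "chest_pain_7d", ]
  expect_equal(cp$n_structured, 1)
  expect_equal(cp$n_either, 1)  # the negated and suspected mentions never count
  expect_equal(cp$pct_increase, 0)

  # structured count of zero leaves the increase undefined
  ev2 <- mk_events(list("p1", "2005-02-27", "182..00", "freetext"))
  tab2 <- symptom_recording_table(ev2, cases)
  expect_true(is.na(tab2$pct_increase[tab2$item == "chest_pain_7d"]))
  expect_equal(tab2$n_either[tab2$item == "chest_pain_7d"], 1)

  empty <- symptom_recording_table(mk_events(list("p1", "2005-02-27", "199..00", "structured")),
                                   cases)
  expect_true(all(empty$n_either[empty$item != "vomiting"] == 0))
})

test_that("symptom table counts a patient once per item and respects windows", {
  cases <- tibble::tibble(patient_id = "p1", mi_date = as.Date("2005-03-01"))
  ev <- mk_events(list("p1", "2005-02-26", "182..00", "structured"),
                  list("p1", "2005-02-27", "182..00", "structured"),
                  list("p1", "2005-01-10", "182..00", "structured"),
                  list("p1", "2005-03-05", "182..00", "structured"))
  tab <- symptom_recording_table(ev, cases)
  expect_equal(tab$n_structured[tab$item == "chest_pain_7d"], 1)   # not 2
  expect_equal(tab$n_structured[tab$item == "chest_pain_90d"], 1)
  # records after the MI never count toward the pre-MI windows
  ev2 <- mk_events(list("p1", "2005-03-05", "182..00", "structured"))
  tab2 <- symptom_recording_table(ev2, cases)
  expect_equal(tab2$n_structured[tab2$item == "chest_pain_7d"], 0)
})
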