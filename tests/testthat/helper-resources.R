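# Shared fixtures, computed once per test run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

test_res <- function() memo("res", default_resources())

mi_exact <- function() memo("mi_exact", generate_mi_cohort(mi_cohort_spec()))

mi_analysis <- function() memo("mi_analysis", analyse_mi_cohort(mi_exact(), test_res()))

death_exact <- function() {
  memo("death_exact", generate_death_cohort(death_cohort_spec(), test_res()))
}

death_cases <- function() memo("death_cases", analyse_deaths(death_exact(), test_res()))

death_report <- function() memo("death_report", concordance_report(death_cases()))

# Write a tiny terminology/synonym/lexicon fixture set; returns the paths.
write_toy_terminology <- function(dir = tempfile("toyterm")) {
  dir.create(dir, showWarnings = FALSE)
  term <- c("code\tterm",
            "G30z.00\tacute myocardial infarction nos",
            "G33..00\tangina pectoris",
            "G575.00\tcardiac arrest",
            "H26..00\tpneumonia",
            "H33..00\tasthma",
            "C10..00\tdiabetes mellitus",
            "K190.00\turinary tract infection",
            "182..00\tchest pain",
            "173..00\tbreathlessness",
            "1M...00\tpain",
            "242..00\tpulse",
            "8H3Z.00\tother hospital admission nos")
  syn <- c("source\ttarget", "uti\turinary tract infection", "mi\tmyocardial infarction")
  lex <- c("the", "no", "patient", "seen", "today")
  paths <- list(term = file.path(dir, "terminology.tsv"),
                syn = file.path(dir, "synonyms.tsv"),
                lex = file.path(dir, "lexicon.txt"))
  writeLines(term, paths$term)
  writeLines(syn, paths$syn)
  writeLines(lex, paths$lex)
  paths
}
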