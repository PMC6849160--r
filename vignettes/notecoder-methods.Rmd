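---
title: "Coding clinical free text and validating phenotypes with notecoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coding clinical free text and validating phenotypes with notecoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notecoder)
library(dplyr)
```

## The problem

UK primary-care records store most clinical detail as Read codes, but a
substantial part of what general practitioners observe — symptoms before a
heart attack, suspected diagnoses, test results, transcribed death
certificates — lives only in short free-text notes. `notecoder` implements a
rule-based entity-linking engine in the style of early GP-record annotators:
it maps sequences of up to five words to a Read-like terminology, detects
the context of each mention (negation, suspicion, medical history), extracts
quantitative results, and emits *only* codes and numbers — a design that
allows the text to be processed where it is held, releasing no raw prose.

On top of the engine sit two phenotyping analyses with registry gold
standards: adjudication of myocardial infarction (MI) subtype (STEMI vs
NSTEMI) against an acute coronary syndrome registry, and extraction of the
underlying cause of death compared with the national death registry. Because
real GP free text cannot be redistributed, the package ships seeded
generators that produce notes and cohorts with known gold annotations; their
default parameters encode a realistic published contingency structure, so
every pipeline stage is testable end to end.

## The engine

The pipeline for each note is:

1. **Cleanup.** An ordered list of literal computer-generated phrases
   (letter headers, automatic entries) is removed. Cleanup is idempotent.
2. **Tokenisation.** Text is lower-cased and split into word, number, date
   and punctuation tokens. Dates are recognised as `dd/mm/yyyy`, `dd.mm.yy`
   and `12 jan 2005`; a/b pairs such as blood pressure readings become two
   number tokens; date-like strings that fail calendar validation degrade to
   word tokens. Newlines always close a sentence because clinical notes
   rarely carry reliable punctuation.
3. **Spelling correction.** A word found in neither the medical lexicon
   (every word of every terminology term, by construction) nor the English
   lexicon is assumed misspelt. The corrector enumerates all single-letter
   insertion and substitution neighbours and accepts the best lexicon word:
   medical before non-medical, then the word occurring in more terms, then
   the lexicographically smallest. Words shorter than 4 characters are never
   corrected — they are almost always abbreviations ("mi", "bp") whose
   nearest dictionary neighbours would corrupt them.
4. **Context attributes.** Ordered cue rules assign one of four attributes:
   `absent` (no, not, denies, nil, without), `suspected` (?, possible,
   suspected, query, likely, probable), `history` (previous, h/o,
   "history of", "*n* year(s) ago"), default `current_or_previous`. A cue
   governs the tokens that follow it in the same sentence up to 6 tokens or
   an adversative conjunction (but, however). When cues conflict the
   precedence is absent > suspected > history, which errs on the side of not
   asserting a condition. The relative-date pattern marks its whole sentence
   as history and dates the event *n*·365 days before the note; an explicit
   date token in a history sentence is used directly.
5. **Matching and scoring.** Every n-gram of 1-5 consecutive word tokens is
   matched against the terminology: exactly, against the head words of a
   longer term (partial coverage), or after up to 2 synonym substitutions
   (1-3-word phrases each). The score is a declared linear function,

   score = coverage − 0.15 · substitutions − 0.10 · corrections,

   where coverage is the fraction of the term's words matched, clipped to
   [0, 1]. An exact full match scores 1; the score never increases with a
   substitution or correction. Candidates below the threshold (default 0.7)
   are dropped; overlaps resolve by longest span, then highest score, then
   fewest substitutions, then lowest code — the last step making output
   fully deterministic. The original engine's scoring function was never
   published, so this formula is this package's own definition; its shape
   (exact beats substituted beats corrected, with a floor) reproduces the
   documented behaviour and every weight is exposed in `engine_config()`.
6. **Quantitative results.** A number within 3 tokens of a matched
   measurable concept (pulse, blood pressure, laboratory counts) binds to
   it, preferring following numbers; blood-pressure pairs fill systolic and
   diastolic; a trailing unit is kept only if it belongs to a closed unit
   vocabulary. Unattached numbers are never emitted. Numbers bind only to
   `current_or_previous` spans.
7. **Safety verification.** `verify_coded_only()` re-checks that every
   emitted code exists in the terminology, every unit is in the closed
   vocabulary, and every categorical field takes enumerated values: the
   coded-output contract that allows on-site processing.

```{r engine-demo}
res <- default_resources()
link_note("p1", "2005-06-01", "no chest pain. ?uti. bp 120/80 mmhg", res) %>%
  select(code, attribute, numeric_value, numeric_value2, unit, score)
```

## The terminology

No licensed Read release can be redistributed, so the package bundles a
small curated terminology (~55 entries) covering the diagnosis, symptom and
test-result codes the analyses and generators need, together with a synonym
table, an English word list, a Read-to-ICD-10 map and a causal-sequence
table. Codes follow Read v2 structure: a 5-character core (dot-padded) plus
a 2-character term suffix; a code is a *diagnosis* exactly when its first
character is an upper-case letter. Terms longer than five words exist in
the terminology but are unreachable from text (the engine's span limit);
free-text statements of MI subtype therefore go through the dedicated
"stemi"/"nstemi" synonym entries, mirroring how Read itself carries synonym
term variants.

## MI subtype adjudication

For each registry case, subtype-bearing records between the MI date and 30
days after are considered; records marked absent or suspected are ignored,
and generic MI codes never produce a call. Structured records take
precedence over free text — the published source tables partition patients
into disjoint "Read code" and "free text" rows, which implies free text was
consulted only when no coded subtype existed. Within a source the record
closest to the MI date wins; an exact tie falls back to entry order (a
documented, deterministic choice — the underlying convention is unknowable
from the tables). Sensitivity, specificity and PPV are computed per class
from the confusion, in structured-only mode (free-text calls count as
unclassified) and combined mode; adding a source can only add calls, so
combined sensitivity is provably never below structured-only sensitivity.

## Cause of death

Post-death records are grouped into three evidence categories, in
decreasing specificity: transcribed death-certificate entries (line markers
1a/1b/1c/ii in text; a certificate-line field on coded events), explicit
statements ("cause of death:" marker), and diagnoses merely dated on or
after death. Selection takes the best category regardless of source,
structured before free text within a category, earliest record within that.

The underlying cause follows a deliberately simplified version of the
WHO selection rules: on a certificate, the lowest used Part-1 line is
underlying if the editable causal-sequence table says it could give rise to
every condition above it (the General Principle); otherwise the
first-mentioned Part-1 condition is selected (the simplified Rule 1/2
fallback); Part-2 conditions are never selected. For non-certificate
evidence the first diagnosis in record order wins, with ill-defined R-chapter
codes deprioritised. The full WHO modification rules are out of scope: the
reference analysis applied them manually, and the simplified rules capture
their effect on the certificates the generators produce, while remaining
transparent and editable.

Agreement with the registry is reported at three nested levels — identical
code, same 3-character category, same chapter — so cumulative proportions
are monotone by construction. The published table calls the middle level a
"2-character code", which would be an unusual unit; the package defaults to
the 3-character category and exposes `icd10_match_chars = 2` for the literal
reading. Group accuracy (coronary I20-I25, cerebrovascular F01 + I60-I69,
cancer C00-C97) is computed on the 3-character category.

## The synthetic generators

`generate_notes()` builds template notes (plain, negated, suspected and
historical mentions, filler sentences, numeric results) with exact gold
annotations. Misspellings are injected only as single deletions or
substitutions *verified to be reversible* by the engine's
insertion/substitution corrector, so correction recall is testable in
isolation; an injected corruption that the corrector would not invert is
abandoned rather than silently breaking the gold standard.

`generate_mi_cohort()` and `generate_death_cohort()` emit event, note and
registry files. Their default parameters are the published contingency
structure itself: 2000 MI patients of whom 608 are registry-linked (315
STEMI / 293 NSTEMI) with the subtype confusion cells as stratum counts;
per-item symptom recording counts; 1800 deaths in three 3-year bands with
the recording-category counts, per-source match-level counts (184/222/278 of
381 free-text; 293/371/463 of 641 coded) and cause-group confusions as
strata. Where the published tables print only percentages, denominators
were back-derived as the unique integer splits consistent with the group
sizes and confidence intervals. Two allocation modes exist: `exact`
reproduces the stratum counts deterministically (table reproduction), and
`sampled` redraws them multinomially (robustness and property tests). The
published per-category accuracy column is arithmetically inconsistent with
the per-source exact-match counts (the rounded accuracies imply at least
304 coded exact matches against 293 printed); the generator honours the
exact counts and distributes them across categories proportionally to the
printed accuracies, reporting the resulting accuracy rather than targeting
it.

What the generators do *not* emulate: realistic clinical language variation
(templates reuse terminology phrasing), out-of-vocabulary concepts,
transcription noise other than single-letter errors, OCR/scanned content
(invisible to text processing by nature), and longitudinal trajectories
beyond the 30/90-day windows. Passing tests therefore demonstrate the
correctness of the rules and arithmetic, not the engine's recall on real
prose.

## Numerical and reporting conventions

All proportions carry Wilson score intervals (default) for their stability
at small counts; Clopper-Pearson is available as an option, and the printed
tables are consistent with either at the reported rounding. Percentages are
rounded half-up to one decimal (metrics) or to integers (percent
increases), matching table formats. Metrics with zero denominators are
reported as undefined (NA), never NaN. Problem sizes in the test suite are
chosen to keep the full run around two minutes on one core: property tests
use corpora of 1500-5000 notes and cohorts of 20-50 patients for brute-force
oracles, while the worked-example reproductions run the full 2000-patient
and 1800-death cohorts.

## Reproducing the analyses

```{r pipelines, eval = FALSE}
mi <- analyse_mi_cohort(generate_mi_cohort(mi_cohort_spec()), res)
tidy(mi$confusion)
mi$metrics

deaths <- analyse_deaths(generate_death_cohort(death_cohort_spec(), res), res)
report <- concordance_report(deaths)
glance(report)
autoplot(report)
```

`scripts/acceptance.R` reruns both pipelines from scratch and writes the
headline quantities as JSON; `inst/cli/notecoder.R` exposes the same
functionality as shell subcommands (`code-text`, `simulate`,
`phenotype-mi`, `death-concordance`).

## Known limitations

- The matcher only recognises term heads (prefix coverage), not arbitrary
  word subsets or reorderings; multi-word terms must appear in term order.
- Negation/suspicion cues scope forward only; post-posed negation
  ("chest pain absent") is not detected.
- The spelling corrector reverses exactly one insertion or substitution;
  transpositions and multi-letter errors are out of scope by design.
- The simplified underlying-cause rules assume well-formed toy
  certificates; real certificates would need the full WHO rule set.
- The bundled terminology is a teaching-scale subset; swapping in a full
  terminology only requires the three TSV lookups.
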