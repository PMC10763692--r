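---
title: "Scoring ADR causality with the Naranjo scale: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring ADR causality with the Naranjo scale: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naranjo)
```

## The instrument

The Naranjo scale (Naranjo et al., 1981) is a structured questionnaire for
judging whether a drug caused an observed adverse event. Ten questions probe
the classical causality criteria — prior reports, temporal association,
dechallenge, rechallenge, alternative causes, placebo response, drug levels,
dose–response, past exposure, and objective confirmation. Each question is
answered *yes*, *no* or *unknown* and contributes an integer weight; the
total score

$$S \;=\; \sum_{q=1}^{10} w(q, a_q)$$

is mapped onto four ordinal categories by closed lower bounds: *Definite*
for $S \ge 9$, *Probable* for $5 \le S \le 8$, *Possible* for
$1 \le S \le 4$, *Doubtful* for $S \le 0$. Over all answer combinations the
total ranges from $-4$ (evidence actively pointing away from the drug) to
$13$ (every criterion maximally positive), and every integer in between is
attainable.

```{r}
naranjo_scale()
```

The scale's assumptions are those of any additive questionnaire: questions
contribute independently, an *unknown* answer is evidence-neutral (weight
0 everywhere), and the same weight applies regardless of the other answers.
The instrument does not model uncertainty in the answers themselves, nor
interactions between criteria.

## Scale as data, not code

`naranjo_scale()` returns the instrument as an immutable, validated value:
question texts, a total weight map over the three response options per
question, and the three category thresholds. All downstream code — scoring,
the console session, batch I/O — reads from this object; nothing else knows
the weights. Two representational choices matter:

* **Thresholds are three lower bounds**, not four ranges. Storing
  `definite_min`, `probable_min`, `possible_min` with a strict-ordering
  invariant guarantees by construction that the integers are partitioned
  exhaustively and disjointly into four bins; printed ranges such as "5–8"
  are only gap-free over integers and would admit inconsistent encodings.
* **"Don't know" and "not known / not done" are one option**, canonically
  `"unknown"`. The instrument's usage treats them interchangeably as the
  single console token `X`, and their weight is 0 in every row, so a split
  would create a distinction without a difference.

A JSON/YAML document loader (`read_scale()` / `write_scale()`) exists so
that tests can build degenerate scales (nine questions, tied thresholds,
missing weights) and assert the validator's diagnostics without ever
touching the built-in constant.

## The scoring core

`assess()` computes per-question contributions, the total, and the category
for one case. Two policies are deliberate:

* **Scores are integers only.** The published weights are integers; no
  fractional or partial-credit variant is offered.
* **Incomplete answer vectors are an error**, with the missing question
  indices listed. Defaulting an unanswered question to *unknown* would
  silently change scores; a caller who wants that behaviour must construct
  the filled-in vector explicitly (the test helpers do exactly this).

`categorize()` is total over the integers — any score, including ones
outside the attainable range, lands in exactly one category — so threshold
logic never needs a special case. It returns an ordered factor, which makes
"the category never decreases" a directly testable comparison.

## Console sessions

`run_session()` reproduces the console workflow: questions prompted in index
order, each input token trimmed, case-folded and classified, invalid tokens
answered with a help line and an immediate re-prompt of the same question.
Decisions taken where the workflow itself is silent:

* **Tokens are case-insensitive** and the full words `yes`/`no`/`unknown`
  are accepted alongside `Y`/`N`/`X`. Broader tokens reduce operator
  friction and introduce no ambiguity; the four token sets must be pairwise
  disjoint after canonicalization, enforced at dialect construction.
* **Retries are unbounded.** The only forced exits are end of input and an
  explicit abort token (`quit`), which a console tool needs; both yield an
  aborted transcript with no result, distinguishable in the event log.
* **The session never re-implements scoring.** A completed run's result is
  literally `assess()` on the accepted answers, and a property test holds
  the two identical over randomized scripts.

Every consumed input line leaves exactly one event (question index, raw
string, outcome) in the transcript, and the displayed lines are part of the
returned object, so a scripted session replays byte-identically — the basis
of the determinism tests and of audit trails via `write_transcript()`.

## Batch scoring

Batch operation is file-driven: CSV with header `case_id,q1,...,q10` and
dialect tokens in the cells, or JSON records with an `answers` object keyed
by question index. The error policy is lenient by default — a malformed row
becomes a per-row error entry carrying the row number and offending cell,
and the batch continues — because a pharmacovigilance batch should not die
on one bad row; `strict = TRUE` escalates the first such row for audit
settings. Structural problems (missing or duplicated header columns,
duplicated case ids) always fail, since they indicate the wrong file rather
than a bad record. Conservation is an invariant: every input case appears
exactly once across `assessments` and `errors`, checked for every batch the
tests construct.

Category labels serialize as the capitalized words `Doubtful` / `Possible` /
`Probable` / `Definite`. Report output is byte-stable: identical reports
produce identical files, so diffs against a stored report are meaningful.

## Synthetic cases and the enumeration oracle

`random_cases()` draws independent answers per question. The default option
probabilities are **uniform (1/3 each)**: no empirical answer distribution
for the instrument has been published, and uniformity exercises all weight
cells and all categories without favouring any. Generation is seeded and
restores the caller's RNG state, so batches reproduce across runs and
platforms. What the generator does *not* emulate is real clinical structure:
answers to related questions (e.g. dechallenge and rechallenge) are
correlated in practice, *unknown* is far more common for placebo and
drug-level questions, and real batches contain narrative metadata. Passing
tests therefore demonstrate correctness of the scoring machinery, not
calibration against clinical ADR data — none is shipped or claimed.

`enumerate_vectors()` is the package's independent oracle. It generates all
$3^{10} = 59{,}049$ complete answer vectors and scores them with **its own
transcription of the published weight table** and its own threshold rule
(interval breaks via `cut()` rather than the `>=` cascade in
`categorize()`). Sharing the `naranjo_scale()` constants would make the
cross-check vacuous; with two independent transcriptions, agreement on all
59,049 vectors checks both the weights and the threshold logic cell for
cell. The property tests assert 100% agreement of totals and categories,
the attainable range $-4..13$ with no gaps, and monotonicity: flipping one
answer to a strictly heavier option strictly increases the total and never
lowers the category. `boundary_cases()` extracts one enumeration witness per
attainable total, covering the 0/1, 4/5 and 8/9 category boundaries.

## Problem sizes and numerical notes

The test suite and `scripts/acceptance.R` run the full 59,049-vector
enumeration (a few seconds), randomized property loops of 10–60 repetitions
under fixed seeds, and a seeded batch of 1,000 uniform cases for the
conservation and round-trip checks. All arithmetic is small-integer; there
are no tolerances, iterative fits or tie-breaks anywhere in the package —
every equality in the tests is exact.

## Limitations

* The package implements one instrument; other causality frameworks
  (e.g. WHO-UMC) are out of scope.
* No drug–drug interaction logic and no ADR prediction: scoring starts from
  the answers a clinician supplies and is only as good as those answers.
* No empirical validation data ships with the package; synthetic cases are
  labelled as such and exist to verify the machinery.
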