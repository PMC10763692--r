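# naranjo

Scoring engine for the **Naranjo adverse drug reaction (ADR) probability
scale**, the 10-question causality-assessment instrument of Naranjo et al.
(1981) used throughout pharmacovigilance to judge how likely it is that a
drug caused an observed adverse event.

Each question is answered *Yes*, *No* or *Unknown* ("don't know / not
done") and contributes an integer number of points `w(q, a)`; the case's
score is the plain sum

```
S = Σ_{q=1}^{10} w(q, a_q),          S ∈ {-4, ..., 13}
```

and `S` maps onto an ordinal causality category:

| Score  | Category |
|--------|----------|
| ≥ 9    | Definite |
| 5 – 8  | Probable |
| 1 – 4  | Possible |
| ≤ 0    | Doubtful |

Most questions award +1 for *Yes*; the temporal-association and rechallenge
questions award +2; the alternative-cause and placebo questions are
reverse-scored; every *Unknown* scores 0.

The package is aimed at pharmacovigilance staff, clinical pharmacologists
and researchers who need reproducible, auditable Naranjo scoring — one case
at a time at the console, or thousands of cases from structured files. It
provides:

* the instrument as validated, immutable data (`naranjo_scale()`), with a
  JSON/YAML document loader so alternative or test scales can be defined
  without touching the built-in constant;
* a pure scoring core (`score_answer()`, `total_score()`, `categorize()`,
  `assess()`) that rejects incomplete answer vectors instead of guessing;
* an interactive console session (`run_session()`) that validates `Y`/`N`/`X`
  tokens, re-prompts on invalid input and logs a replayable transcript;
* batch scoring (`read_cases()`, `score_batch()`, `write_report()`) with
  per-row error capture and a category-count summary;
* synthetic-case generation (`random_cases()`, `boundary_cases()`) and an
  independent exhaustive-enumeration oracle (`enumerate_vectors()`) that
  re-scores all 3^10 = 59,049 possible answer vectors through a separate
  code path.

## Worked example

A suspected amoxicillin rash: previous reports exist (Q1 yes), the rash
followed the drug (Q2 yes) and improved on dechallenge (Q3 yes), no
rechallenge was attempted (Q4 unknown), no alternative cause (Q5 no), no
placebo given (Q6 unknown), no drug level measured (Q7 unknown), the rash
worsened at higher dose (Q8 yes), no prior exposure reaction (Q9 no), and
the rash was objectively documented (Q10 yes):

```r
library(naranjo)
scale <- naranjo_scale()
assess(scale,
       c(q1 = "yes", q2 = "yes", q3 = "yes", q4 = "unknown", q5 = "no",
         q6 = "unknown", q7 = "unknown", q8 = "yes", q9 = "no", q10 = "yes"),
       case_id = "amoxicillin-rash")
#> <naranjo_assessment> case 'amoxicillin-rash' (scale naranjo/1981)
#>   Q1  yes      +1
#>   Q2  yes      +2
#>   Q3  yes      +1
#>   Q4  unknown  +0
#>   Q5  no       +2
#>   Q6  unknown  +0
#>   Q7  unknown  +0
#>   Q8  yes      +1
#>   Q9  no       +0
#>   Q10 yes      +1
#>   Total score: 8
#>   Category: Probable ADR
```

A total of 8 points falls in the 5–8 band, so the reaction is classed a
*Probable* ADR — one point short of *Definite*, which would additionally
require e.g. a positive rechallenge.

## Command line

A thin CLI over the same functions ships in `inst/cli/naranjo.R`
(`system.file("cli", "naranjo.R", package = "naranjo")` after install):

```sh
Rscript inst/cli/naranjo.R assess --case-id c1 --transcript-out c1.json
Rscript inst/cli/naranjo.R batch --in cases.csv --out report.csv --summary summary.csv
Rscript inst/cli/naranjo.R fixtures --n 100 --seed 7 --out cases.csv
```

Batch CSV input has a header `case_id,q1,...,q10` with `Y`/`N`/`X` (or
full-word) cells; malformed rows are reported per row and skipped unless
`--strict` is given.

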