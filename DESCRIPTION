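Package: naranjo
Title: Naranjo Adverse Drug Reaction Probability Scale
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scoring engine for the Naranjo adverse drug reaction (ADR)
    probability scale, a 10-question causality-assessment instrument that
    assigns integer points per answer (Yes/No/Unknown) and maps the summed
    score to an ordinal category (Doubtful, Possible, Probable, Definite).
    Provides the canonical instrument as validated immutable data, per-case
    and batch scoring with per-row error capture, an interactive console
    session with token validation and re-prompting, seeded synthetic case
    generation, and an independent exhaustive-enumeration oracle over all
    59,049 answer vectors for property-based verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
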