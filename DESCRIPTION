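Package: examaudit
Title: Ambiguity Detection and Quality Scoring for Exam Item Banks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A priori quality control for academic exams. Grades candidate
    and model responses against answer keys with a discrepancy-based
    partial-credit rubric, summarizes the disagreement of an ensemble of
    large-language-model responders per question, assigns four binary
    diagnostic tags (ambiguity, low performance, incoherence, subjective
    ambiguity), derives a composite ambiguity score and ambiguity-weighted
    component quality scores with qualitative bands, compares score
    distributions with a normality-gated test choice, and validates the
    whole detector on synthetic exams with planted ambiguity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
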