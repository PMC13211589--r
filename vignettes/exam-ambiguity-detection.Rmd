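---
title: "Detecting ambiguous exam items with an LLM ensemble: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ambiguous exam items with an LLM ensemble: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(examaudit)
```

## The problem

Exam items are usually audited *a posteriori*: after students sit the
exam, items with pathological response patterns are discarded, at a cost
in fairness, time and credibility. `examaudit` implements an *a priori*
alternative: submit every item to an ensemble of general-purpose large
language models, grade their answers against the official key exactly as
student answers would be graded, and read signs of structural fragility —
ambiguous wording, multiple defensible keys, misleading stems — out of
the ensemble's disagreement pattern. The models act as screening agents,
not judges: everything the detector flags is meant for human review.

## Grading model

A multi-select response is compared to the answer key by counting
**discrepancies**: options selected but not in the key, plus key options
not selected — the cardinality of the symmetric difference between the
two sets. Both error directions are treated symmetrically; this is the
only symmetric count consistent with penalising both false positives and
omissions. The partial-credit rubric maps discrepancy counts to fractions
of the item maximum:

| discrepancies | 0 | 1 | 2 | > 2 |
|---|---|---|---|---|
| fraction of max | 1 | 0.5 | 0.2 | 0 |

The rubric is expressed as *fractions* rather than absolute points so that
normalized scores stay in [0, 1] for any `max_points`; it is configurable
(`thresholds(rubric = ...)`) so other faculties' rubrics can be expressed.
Design notes:

* **Single-best-answer items** are graded by the same rule, so a wrong
  single option (one selected in error + one omitted = 2 discrepancies)
  earns 0.2 of the maximum. Faculties that score SBA all-or-nothing can
  set `sba_all_or_nothing = TRUE`.
* **Abstention** (an empty selection) is graded by the same rule and
  counts `|key|` discrepancies — it is a valid response, not an error.
* **Short-answer questions** cannot be auto-graded; they enter as
  pre-graded points and pass through unchanged.

Exam totals are normalized to a 20-point scale,
`20 * sum(points) / sum(max_points)`, with the pass mark at 10/20 (a score
exactly at the mark passes).

## Ensemble metrics and tags

Per item, over the model responders only: the mean and SD of normalized
scores, the number of models scoring below 1 ("failed to answer
correctly" — any discrepancy counts, configurable via
`incorrect_cutoff`), the number of **distinct** wrong answers among them,
and the number of ambiguity self-reports. Wrong answers are distinct when
their selected-option sets differ (order in the cell is irrelevant); for
short-answer items, when their whitespace/case-normalized answer texts
differ, falling back to the graded points when no text is recorded.
Identical wrong answers deliberately collapse: several models converging
on the same wrong answer indicates a shared misconception, not an
ambiguous item.

The SD uses the sample estimator (n − 1) by default; with only four
ensemble members the choice is material, and the population estimator is
available (`sd_estimator = "population"`). The default is pinned by the
test suite.

The four binary tags and the composite score:

* **ambiguity** — `n_incorrect >= 2` and `n_distinct_wrong >= 2`;
* **low performance** — `mean < 0.5` and `SD < 0.3`;
* **incoherence** — `SD > 0.3`;
* **subjective ambiguity** — `n_ambiguity_reports >= 2`;
* **ambiguity score** `A_i` = sum of the four.

All threshold comparisons are strict, as printed above. At SD exactly 0.3
neither SD tag fires; this is intentional and tested. Because the two SD
tags are mutually exclusive, the maximum reachable score is 3, with labels
0 "No issues detected", 1 "Minor concern", 2 "Moderate ambiguity", 3
"Strong signal of item flaw or misleading structure". `assign_tags()`
raises an internal error if a score above 3 is ever produced — a tripwire
that should be unreachable.

The count thresholds ("at least 2 of 4") and the 0.5 / 0.3 splits are
defaults appropriate for a 4-member ensemble. `elbow_threshold()` offers
a data-driven check: values are sorted in decreasing order, both axes are
min-max normalized, and the point of maximum perpendicular distance to
the chord joining the first and last points is the transition from
typical to anomalous values (a Kneedle-style knee without smoothing —
sample sizes here are too small for kernel smoothing to help). Ties break
toward the earlier sorted index, compared with a 1e-12 tolerance so the
rule is not at the mercy of floating-point noise; curves whose maximum
distance falls below `flat_tol = 0.02` (normalized units) have no elbow
and return `NA`. Elbow output is advisory — the canonical defaults above
are what the tags use.

## Component quality

Item quality is `Q_i = 20 * S_i`, where `S_i` is the ensemble mean of
normalized model scores including partial credit. The component score is
the weighted mean with ambiguity weights `w_i = 1 / (1 + A_i)`
(1, 1/2, 1/3, 1/4): a flagged item still contributes, but its evidence is
discounted in proportion to how many independent failure signals it
carries. The score is a convex combination, hence bounded by the extreme
`Q_i`.

Band intervals share their printed endpoints, so they are resolved as
half-open `[lower, upper)` with the top band closed at 20. The review
rule ("below 15") forces 15 itself into the upper band: a component
scoring exactly 15/20 is "very good" and not flagged. `needs_review` is
strict (`score < 15`).

## Statistical comparisons

`compare_samples()` implements the normality-gated choice: Shapiro-Wilk
on *each* sample at α = 0.05 (the gate requires both to pass — the
procedure is deliberately conservative about which distribution "the"
normality refers to), then a Student two-tailed t test (equal variances)
or a two-sided Mann-Whitney U test. The Mann-Whitney p is exact when both
samples have ≤ 8 observations and no ties, and uses the normal
approximation with continuity and tie correction otherwise. Constant
samples, for which Shapiro-Wilk is undefined, are routed to the rank
test. Samples smaller than 5 trigger a warning — comparing a 4-member
ensemble to a cohort is statistically fragile — but are still computed,
with `gate = "force_mw"` / `"force_t"` available below n = 3. No
multiple-testing correction is applied across pairwise comparisons.

Both tests delegate to the reference implementations in `stats`; the test
suite cross-checks them against an independent brute-force rank
enumeration (exact Mann-Whitney, n ≤ 8) and a closed-form Student t
recomputation.

## The synthetic-exam generator

No exam corpus ships with the package, so validation rests on simulation
with known ground truth. The generator emulates the study design the
detector targets: a bank of five-option multi-select items grouped into
components (5 components × 40 items = 200 questions by default), a
student cohort, and a 4-member model ensemble.

* **Ambiguity is planted as multiple plausible keys.** With prevalence
  π = 0.3, an item carries `k_readings = 2` keys: the official one and an
  alternative differing by exactly two option flips. On such an item each
  model independently commits to the alternative reading with probability
  0.8, then answers *its* reading's key with per-option competence 0.95
  (each key option selected, each distractor rejected, independently).
  Models self-report ambiguity with probability 0.6 on planted items and
  0.05 on clean ones.
* **Why two option flips?** A single-flip alternative answered perfectly
  yields a normalized score of exactly 0.5 with zero ensemble dispersion
  and one shared wrong answer — a configuration that evades every
  performance-based tag *by construction* (the thresholds are strict
  inequalities). The planted effect is meant to be strong and detectable
  through disagreement; a two-flip alternative puts a committed
  alternative reading unambiguously in the wrong (0.2 credit), which is
  what "a plausible but incorrect reading of the item" should look like
  to the detector.
* **Students** answer option-by-option with success probability
  `plogis(ability − difficulty)`; abilities are N(1.5, 1) on the logit
  scale and difficulties N(0, 1), which lands simulated cohort means
  around 11–14 of 20 — the range a realistic cohort occupies. Ambiguous
  items mix the success probability toward a coin flip with weight 0.3.
* **Seeding.** A root seed feeds per-stage, per-question substreams
  (`substream_seed()`), so a fixed seed reproduces the dataset
  byte-for-byte and regenerating one stage does not disturb another.

What the simulator does *not* model: correlated errors between models
(architectures sharing training data), within-case learning across
sequenced questions, item formats other than multi-select MCQ, and
self-reports that depend on the model's actual confusion rather than on
ground truth. Passing the recovery tests therefore shows the detector's
rules are internally consistent and sensitive to the planted mechanism —
not that real LLM disagreement behaves like the toggle model.

### Detection and null properties

Two properties pin the detector end to end, at the strong-effect
settings above (200 items, fixed seed):

* flagging at `ambiguity_score >= 2` recovers planted items with
  sensitivity > 0.7 and specificity > 0.8, and planted items carry a
  strictly higher mean score than clean ones;
* a null run (π = 0) with highly reliable models flags fewer than 5% of
  items. The null run uses competence 0.98: the specificity question it
  answers is "does the detector invent ambiguity on clean items answered
  by reliable models", and at 0.95 roughly 2% of answers carry two
  discrepancies from per-option noise alone — a property of the noise
  model, not of the items. In practice the detector sits well inside both
  bounds (sensitivity ≈ 0.88–0.95, specificity ≈ 0.93–0.97 across seeds).

## Degenerate inputs and other conventions

* Duplicate response records (e.g. the same answer submitted under both
  prompt-input formats) collapse when identical and raise an error when
  conflicting; scoring can be restricted to one input format
  (`restrict_input_format`), and the format label is otherwise ignored by
  all scoring.
* Option labels are opaque, case-sensitive tokens; only surrounding
  whitespace is stripped. Multi-valued cells use a `|` separator.
* An empty component, a responder missing items, a key outside the option
  universe, or a student record carrying an ambiguity self-report are
  hard errors naming the offending rows.
* Reported percentages round half *up* to one decimal (commercial
  rounding), matching the convention of the reporting style the package
  follows; base R's round-half-to-even would print e.g. 0.25% as 0.2%.

## Problem sizes

The test suite validates on banks of 20–300 items, cohorts up to 120
students, and a 4-model ensemble; property tests run 1,000 randomized
tag-assignment draws and exhaustive enumerations where the space is small
(all 32 selection subsets of a 5-option item, all 16 tag vectors, all
rank assignments for exact Mann-Whitney at n ≤ 8). The full suite runs in
well under a minute.

## Limitations

The detector inherits the pilot character of its method: tags are
indicators of structural fragility, not proof of item flaws; the
subjective-ambiguity tag relies on model self-assessment with criteria
the models define themselves; and thresholds tuned for a 4-member
ensemble should be re-derived (e.g. with `elbow_threshold()`) for other
ensemble sizes. Free-text items are only as good as their human
pre-grading, and the simulator's independence assumptions are optimistic
about real model ensembles.
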