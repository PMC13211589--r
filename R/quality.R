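#' @title Component quality scores with ambiguity weighting
#' @description
#' Each question's quality is its mean normalized ensemble score rescaled
#' to 20 points, `Q_i = 20 * S_i`. A component's quality is the weighted
#' mean of its questions' `Q_i` with weights `w_i = 1 / (1 + A_i)`, where
#' `A_i` is the composite ambiguity score — flagged questions count less,
#' so a component is judged mostly on its clean items. Scores map to
#' qualitative bands; components scoring below 15/20 need review.
#' @name quality_scoring
NULL

quality_bands <- tibble::tibble(
  band = c("excellent", "very_good", "moderate", "poor", "insufficient"),
  lower = c(18, 15, 12, 10, 0),
  upper = c(20, 18, 15, 12, 10)
)

#' Question quality on the 20-point scale
#'
#' @param mean_score Mean normalized ensemble score `S_i` in \[0, 1\].
#' @return `20 * mean_score`.
#' @export
question_quality <- function(mean_score) {
  stopifnot(all(mean_score >= 0 & mean_score <= 1))
  20 * mean_score
}

#' Ambiguity weight of a question
#'
#' @param ambiguity_score Composite ambiguity score `A_i` in 0..3.
#' @return `1 / (1 + ambiguity_score)`, i.e. 1, 1/2, 1/3 or 1/4.
#' @export
ambiguity_weight <- function(ambiguity_score) {
  if (any(!ambiguity_score %in% 0:3)) {
    stop("ambiguity scores must lie in 0..3", call. = FALSE)
  }
  1 / (1 + ambiguity_score)
}

#' Weighted component score
#'
#' @param quality Vector of question qualities `Q_i` (20-point scale).
#' @param weights Vector of weights `w_i`, same length, all positive.
#' @return `sum(Q_i * w_i) / sum(w_i)`.
#' @export
component_score <- function(quality, weights) {
  if (length(quality) == 0) stop("empty component", call. = FALSE)
  if (length(quality) != length(weights)) {
    stop("quality and weights differ in length", call. = FALSE)
  }
  stopifnot(all(weights > 0))
  sum(quality * weights) / sum(weights)
}

#' Qualitative band of a component score
#'
#' Bands partition \[0, 20\] with half-open intervals, closed at the top:
#' \[18, 20\] excellent, \[15, 18) very good, \[12, 15) moderate,
#' \[10, 12) poor, \[0, 10) insufficient. A score of exactly 15 is "very
#' good" (only components *below* 15 are re-reviewed).
#'
#' @param score Numeric vector on the 20-point scale.
#' @return Character vector of band labels.
#' @examples
#' band(c(20, 16.67, 15, 14.99, 9.99))
#' @export
band <- function(score) {
  if (any(score < 0 | score > 20)) {
    stop("component scores live on the 20-point scale", call. = FALSE)
  }
  vapply(score, function(s) {
    i <- which(s >= quality_bands$lower &
                 (s < quality_bands$upper | (s == 20 & quality_bands$upper == 20)))
    quality_bands$band[i[1]]
  }, character(1))
}

#' Per-component quality table
#'
#' Joins the per-question metrics and tags, computes `Q_i` and `w_i`, and
#' aggregates per component of the bank.
#'
#' @param metrics Output of [summarize_questions()].
#' @param tags Output of [assign_tags()].
#' @param bank The `question_bank` (defines component membership).
#' @param config A [thresholds()] object (`review_cutoff`).
#' @return Tibble: `component_id`, `dtype`, `n_questions`,
#'   `component_score`, `band`, `needs_review`, plus author metadata
#'   carried from the bank.
#' @export
component_quality <- function(metrics, tags, bank,
                              config = default_thresholds()) {
  per_q <- dplyr::inner_join(tibble::as_tibble(metrics),
                             tibble::as_tibble(tags), by = "question_id")
  per_q$quality <- question_quality(per_q$mean_score)
  per_q$weight <- ambiguity_weight(per_q$ambiguity_score)
  comp <- bank$components
  out <- purrr::map_dfr(seq_len(nrow(comp)), function(i) {
    ids <- split_opts(comp$question_ids[i])
    rows <- per_q[per_q$question_id %in% ids, ]
    if (nrow(rows) == 0) {
      stop("component ", comp$component_id[i],
           " has no scored questions", call. = FALSE)
    }
    sc <- component_score(rows$quality, rows$weight)
    tibble::tibble(
      component_id = comp$component_id[i],
      dtype = comp$dtype[i],
      author_specialty = comp$author_specialty[i],
      author_rank = comp$author_rank[i],
      cohort_label = comp$cohort_label[i],
      n_questions = nrow(rows),
      component_score = sc,
      band = band(sc),
      needs_review = sc < config$review_cutoff
    )
  })
  out
}

#' Per-question quality detail
#'
#' Convenience join of metrics, tags, `Q_i` and `w_i` per question.
#'
#' @inheritParams component_quality
#' @return Tibble with one row per question.
#' @export
question_quality_table <- function(metrics, tags, bank) {
  per_q <- dplyr::inner_join(tibble::as_tibble(metrics),
                             tibble::as_tibble(tags), by = "question_id")
  per_q$component_id <- bank$questions$component_id[
    match(per_q$question_id, bank$questions$question_id)]
  per_q$quality <- question_quality(per_q$mean_score)
  per_q$weight <- ambiguity_weight(per_q$ambiguity_score)
  per_q
}
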