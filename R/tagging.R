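#' @title Diagnostic tags and the composite ambiguity score
#' @description
#' Four binary tags diagnose distinct failure modes of an item, from the
#' per-question ensemble summary:
#' * **ambiguity** — at least 2 models wrong with at least 2 *different*
#'   wrong answers (diverging interpretations, not a shared misconception);
#' * **low performance** — mean normalized score strictly below 0.5 with
#'   SD strictly below 0.3 (uniform failure: likely unanswerable or flawed);
#' * **incoherence** — SD strictly above 0.3 (models scatter);
#' * **subjective ambiguity** — at least 2 models self-report ambiguity.
#'
#' The composite ambiguity score is the sum of the four tags. Because low
#' performance and incoherence depend on opposite strict SD thresholds
#' they are mutually exclusive, so the score ranges 0-3.
#' @name tagging_engine
NULL

ambiguity_labels <- c(
  "0" = "No issues detected",
  "1" = "Minor concern",
  "2" = "Moderate ambiguity",
  "3" = "Strong signal of item flaw or misleading structure"
)

#' Assign the four diagnostic tags to question metrics
#'
#' @param metrics Tibble from [summarize_questions()] (or any tibble with
#'   its columns).
#' @param config A [thresholds()] object.
#' @return Tibble: `question_id`, the four 0/1 tags (`ambiguity`,
#'   `low_performance`, `incoherence`, `subjective_ambiguity`),
#'   `ambiguity_score` and its qualitative `label`.
#' @export
assign_tags <- function(metrics, config = default_thresholds()) {
  m <- tibble::as_tibble(metrics)
  amb <- as.integer(m$n_incorrect >= config$min_wrong_models &
                      m$n_distinct_wrong >= config$min_distinct_wrong)
  low <- as.integer(m$mean_score < config$low_perf_mean &
                      m$sd_score < config$sd_split)
  inc <- as.integer(m$sd_score > config$sd_split)
  subj <- as.integer(m$n_ambiguity_reports >= config$min_ambiguity_reports)
  score <- amb + low + inc + subj
  if (any(low + inc > 1)) {
    stop("internal error: low_performance and incoherence fired together",
         call. = FALSE)  # unreachable with opposing strict SD thresholds
  }
  if (any(score > 3)) {
    stop("internal error: ambiguity score above 3 is unreachable",
         call. = FALSE)  # tripwire
  }
  tibble::tibble(
    question_id = m$question_id,
    ambiguity = amb,
    low_performance = low,
    incoherence = inc,
    subjective_ambiguity = subj,
    ambiguity_score = score,
    label = score_label(score)
  )
}

#' Qualitative label for a composite ambiguity score
#'
#' @param ambiguity_score Integer vector in 0..3.
#' @return Character vector of labels.
#' @examples
#' score_label(0:3)
#' @export
score_label <- function(ambiguity_score) {
  if (any(!ambiguity_score %in% 0:3)) {
    stop("ambiguity scores must lie in 0..3", call. = FALSE)
  }
  unname(ambiguity_labels[as.character(ambiguity_score)])
}

#' Frequency table of tag combinations
#'
#' Counts how often each distinct subset of the four tags occurs and the
#' share of all items it represents (percent, half-up rounded to one
#' decimal). Items with no tag are reported as `"none"`.
#'
#' @param tags Output of [assign_tags()].
#' @return Tibble: `combination` ("+"-joined tag names), `n`, `percent`,
#'   sorted by decreasing count.
#' @export
tag_combinations <- function(tags) {
  tags <- tibble::as_tibble(tags)
  if (nrow(tags) == 0) {
    return(tibble::tibble(combination = character(), n = integer(),
                          percent = numeric()))
  }
  tag_cols <- c("ambiguity", "low_performance", "incoherence",
                "subjective_ambiguity")
  combo <- vapply(seq_len(nrow(tags)), function(i) {
    on <- tag_cols[unlist(tags[i, tag_cols]) == 1]
    if (length(on) == 0) "none" else paste(on, collapse = "+")
  }, character(1))
  tab <- dplyr::count(tibble::tibble(combination = combo), .data$combination,
                      sort = TRUE)
  tab$percent <- round_half_up(100 * tab$n / nrow(tags), 1)
  tab
}
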