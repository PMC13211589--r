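#' @title Per-question ensemble summaries and elbow-point thresholds
#' @name ensemble_metrics
NULL

# Canonical signature of one model's answer, used to decide whether two
# wrong answers are "the same answer". MCQ-type: the selected-option set
# (order-insensitive). SAQ: whitespace/case-normalized answer text, falling
# back to the graded points when no text is recorded.
answer_signature <- function(format, selected, answer_text, graded_points) {
  if (format == "SAQ") {
    if (!is.na(answer_text) && nzchar(trimws(answer_text))) {
      paste0("text:", tolower(gsub("\\s+", " ", trimws(answer_text))))
    } else {
      paste0("points:", format(graded_points, digits = 15))
    }
  } else {
    paste0("set:", canonical_set(selected))
  }
}

#' Summarize the model ensemble's behaviour per question
#'
#' For every question answered by at least one model responder, computes
#' the mean and SD of the models' normalized scores, the number of models
#' that failed to answer correctly (normalized score strictly below
#' `incorrect_cutoff`, default 1), the number of *distinct* wrong answers
#' among them (identical wrong answers collapse: several models converging
#' on the same wrong answer signals a shared misconception, not
#' ambiguity), and the number of models self-reporting ambiguity.
#'
#' @param graded Output of [grade_responses()].
#' @param responses The `response_table` the grades came from (supplies the
#'   answer content and ambiguity flags).
#' @param bank The `question_bank`.
#' @param config A [thresholds()] object (`sd_estimator`,
#'   `incorrect_cutoff`).
#' @return Tibble with columns `question_id`, `mean_score`, `sd_score`,
#'   `n_incorrect`, `n_distinct_wrong`, `n_ambiguity_reports`, `n_models`.
#' @export
summarize_questions <- function(graded, responses, bank,
                                config = default_thresholds()) {
  responses <- response_table(responses)
  g <- graded[graded$responder_kind == "model", ]
  if (nrow(g) == 0) stop("no model responders to summarize", call. = FALSE)
  r <- responses[responses$responder_kind == "model", ]
  g <- dplyr::left_join(
    g,
    r[, c("responder_id", "question_id", "selected", "answer_text",
          "graded_points", "ambiguity_report")],
    by = c("responder_id", "question_id")
  )
  g$format <- bank$questions$format[match(g$question_id, bank$questions$question_id)]
  sd_fun <- if (config$sd_estimator == "population") {
    function(x) sqrt(mean((x - mean(x))^2))
  } else {
    function(x) if (length(x) == 1) 0 else stats::sd(x)
  }
  out <- purrr::map_dfr(split(g, g$question_id), function(q) {
    wrong <- q[q$normalized < config$incorrect_cutoff, ]
    sigs <- vapply(seq_len(nrow(wrong)), function(i) {
      answer_signature(wrong$format[i], wrong$selected[i],
                       wrong$answer_text[i], wrong$graded_points[i])
    }, character(1))
    tibble::tibble(
      question_id = q$question_id[1],
      mean_score = mean(q$normalized),
      sd_score = sd_fun(q$normalized),
      n_incorrect = nrow(wrong),
      n_distinct_wrong = length(unique(sigs)),
      n_ambiguity_reports = sum(q$ambiguity_report, na.rm = TRUE),
      n_models = nrow(q)
    )
  })
  # report in bank order
  out[order(match(out$question_id, bank$questions$question_id)), ]
}

#' Elbow-point threshold of a metric distribution
#'
#' Kneedle-style knee detection without smoothing: the values are sorted
#' in decreasing order, both axes are min-max normalized, and the point at
#' maximum perpendicular distance from the chord joining the first and
#' last sorted points is the elbow — the transition from typical to
#' anomalous values. Ties break toward the earlier sorted index. When the
#' maximum distance falls below `flat_tol` (the curve is essentially
#' straight, so there is no transition), `NA` is returned.
#'
#' @param values Numeric vector, length at least 3.
#' @param flat_tol Flatness tolerance in normalized units (default 0.02).
#' @return The value at the elbow, or `NA_real_` when the curve is flat.
#' @examples
#' elbow_threshold(c(100, 99, 98, 5, 4, 3)) # 98
#' elbow_threshold(1:100)                   # NA: linear, no curvature
#' @export
elbow_threshold <- function(values, flat_tol = 0.02) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    stop("elbow detection needs at least 3 values", call. = FALSE)
  }
  v <- sort(values, decreasing = TRUE)
  n <- length(v)
  x <- (seq_len(n) - 1) / (n - 1)
  rng <- diff(range(v))
  if (rng == 0) return(NA_real_)
  y <- (v - min(v)) / rng
  # perpendicular distance to the chord from (x1, y1) to (xn, yn)
  dx <- x[n] - x[1]
  dy <- y[n] - y[1]
  d <- abs(dy * x - dx * y + dx * y[1] - dy * x[1]) / sqrt(dx^2 + dy^2)
  if (max(d) < flat_tol) return(NA_real_)
  # ties (up to floating-point noise) break toward the earlier sorted index
  v[which(d >= max(d) - 1e-12)[1]]
}
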