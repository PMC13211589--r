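#' @title Discrepancy-based partial-credit grading
#' @description
#' A response to a multi-select item is scored by counting discrepancies —
#' options selected that are not in the key plus key options left
#' unselected, i.e. the symmetric difference between the selected set and
#' the answer key — and mapping that count through the faculty rubric:
#' full marks for 0 discrepancies, 0.5 of the maximum for 1, 0.2 for 2,
#' nothing beyond 2. Free-text (SAQ) answers arrive pre-graded and pass
#' through. Exam totals are normalized to a 20-point scale with a pass
#' mark of 10.
#' @name grading
NULL

#' Count discrepancies between a selected set and the answer key
#'
#' The discrepancy count is the cardinality of the symmetric difference:
#' wrongly selected options plus omitted key options. An abstention (empty
#' selection) therefore counts `length(key)` discrepancies.
#'
#' @param key Character vector: the answer key.
#' @param selected Character vector: the selected options.
#' @param options Character vector: the item's option universe.
#' @return Integer discrepancy count.
#' @examples
#' count_discrepancies(c("A", "C"), c("A", "B"), LETTERS[1:5]) # 2
#' @export
count_discrepancies <- function(key, selected, options) {
  key <- unique(key)
  selected <- unique(selected)
  if (!all(key %in% options)) {
    stop("key option(s) outside the option universe: ",
         paste(setdiff(key, options), collapse = ", "), call. = FALSE)
  }
  if (!all(selected %in% options)) {
    stop("selected option(s) outside the option universe: ",
         paste(setdiff(selected, options), collapse = ", "), call. = FALSE)
  }
  length(setdiff(key, selected)) + length(setdiff(selected, key))
}

#' Map a discrepancy count to points
#'
#' The rubric is expressed as fractions of `max_points`, indexed by
#' discrepancy count starting at 0; counts beyond the rubric's length score
#' 0. The default `c(1, 0.5, 0.2)` awards full marks, half marks, a fifth,
#' then nothing.
#'
#' @param discrepancies Non-negative integer vector.
#' @param max_points Positive item maximum (default 1).
#' @param rubric Fractions of `max_points` for 0, 1, 2, ... discrepancies.
#' @return Points awarded, same length as `discrepancies`.
#' @examples
#' partial_credit(0:3) # 1.0 0.5 0.2 0.0
#' @export
partial_credit <- function(discrepancies, max_points = 1,
                           rubric = c(1, 0.5, 0.2)) {
  stopifnot(all(discrepancies >= 0), all(max_points > 0))
  frac <- ifelse(discrepancies < length(rubric), rubric[discrepancies + 1], 0)
  frac * max_points
}

#' Grade one response against its question
#'
#' @param question One-row slice of a bank's `questions` tibble (or a list
#'   with the same fields).
#' @param record One-row slice of a `response_table` (or equivalent list).
#' @param config An [thresholds()] object carrying the rubric.
#' @return One-row tibble: `responder_id`, `question_id`, `discrepancies`
#'   (`NA` for SAQ), `points`, `normalized`.
#' @export
grade_response <- function(question, record, config = default_thresholds()) {
  question <- as.list(question)
  record <- as.list(record)
  if (record$question_id != question$question_id) {
    stop("record answers question ", record$question_id,
         ", not ", question$question_id, call. = FALSE)
  }
  maxp <- question$max_points %||% 1
  if (question$format == "SAQ") {
    if (is.na(record$graded_points %||% NA_real_)) {
      stop("SAQ response for ", question$question_id,
           " has no graded_points", call. = FALSE)
    }
    pts <- record$graded_points
    if (pts < 0 || pts > maxp) {
      stop("graded_points for ", question$question_id,
           " outside [0, max_points]", call. = FALSE)
    }
    disc <- NA_integer_
  } else {
    if (is.na(record$selected %||% NA_character_)) {
      stop("MCQ-type response for ", question$question_id,
           " has no selected set", call. = FALSE)
    }
    disc <- count_discrepancies(split_opts(question$key),
                                split_opts(record$selected),
                                split_opts(question$options))
    if (question$format == "SBA" && config$sba_all_or_nothing && disc > 0) {
      pts <- 0
    } else {
      pts <- partial_credit(disc, maxp, config$rubric)
    }
  }
  tibble::tibble(
    responder_id = record$responder_id,
    question_id = question$question_id,
    discrepancies = as.integer(disc),
    points = pts,
    normalized = pts / maxp
  )
}

#' Grade a response table against a question bank
#'
#' Identical duplicate rows (e.g. the same answer submitted under both
#' input formats) collapse to one; conflicting duplicates for the same
#' responder and question raise an error naming them. If the configuration
#' restricts scoring to one input format, rows carrying the other label
#' are dropped first.
#'
#' @param bank A `question_bank`.
#' @param responses A `response_table`.
#' @param config A [thresholds()] object.
#' @return Tibble with one graded row per responder x question, carrying
#'   `responder_kind` through.
#' @export
grade_responses <- function(bank, responses, config = default_thresholds()) {
  responses <- response_table(responses)
  if (!is.null(config$restrict_input_format)) {
    responses <- responses[is.na(responses$input_format) |
                             responses$input_format == config$restrict_input_format, ]
  }
  unknown <- setdiff(responses$question_id, bank$questions$question_id)
  if (length(unknown) > 0) {
    stop("response(s) reference unknown question(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  # collapse exact duplicates (answer content, not metadata), then detect conflicts
  key_cols <- c("responder_id", "question_id", "selected", "graded_points")
  dedup <- dplyr::distinct(responses, dplyr::across(dplyr::all_of(key_cols)),
                           .keep_all = TRUE)
  dup <- dplyr::count(dedup, .data$responder_id, .data$question_id)
  dup <- dup[dup$n > 1, ]
  if (nrow(dup) > 0) {
    stop("conflicting duplicate responses for: ",
         paste(paste0(dup$responder_id, "/", dup$question_id), collapse = ", "),
         call. = FALSE)
  }
  # vectorized grading: per-question key/option sets are computed once
  qs <- bank$questions
  key_sets <- lapply(qs$key, split_opts)
  opt_sets <- lapply(qs$options, split_opts)
  qidx <- match(dedup$question_id, qs$question_id)
  fmt <- qs$format[qidx]
  maxp <- qs$max_points[qidx]

  disc <- rep(NA_integer_, nrow(dedup))
  pts <- rep(NA_real_, nrow(dedup))
  mcq <- fmt != "SAQ"
  if (any(mcq & is.na(dedup$selected))) {
    bad <- which(mcq & is.na(dedup$selected))[1]
    stop("MCQ-type response for ", dedup$question_id[bad],
         " has no selected set", call. = FALSE)
  }
  if (any(!mcq & is.na(dedup$graded_points))) {
    bad <- which(!mcq & is.na(dedup$graded_points))[1]
    stop("SAQ response for ", dedup$question_id[bad],
         " has no graded_points", call. = FALSE)
  }
  disc[mcq] <- vapply(which(mcq), function(i) {
    count_discrepancies(key_sets[[qidx[i]]], split_opts(dedup$selected[i]),
                        opt_sets[[qidx[i]]])
  }, integer(1))
  pts[mcq] <- partial_credit(disc[mcq], maxp[mcq], config$rubric)
  if (config$sba_all_or_nothing) {
    zero <- mcq & fmt == "SBA" & disc > 0
    pts[zero] <- 0
  }
  saq_pts <- dedup$graded_points[!mcq]
  if (any(saq_pts < 0 | saq_pts > maxp[!mcq])) {
    stop("graded_points outside [0, max_points]", call. = FALSE)
  }
  pts[!mcq] <- saq_pts
  tibble::tibble(
    responder_id = dedup$responder_id,
    responder_kind = dedup$responder_kind,
    question_id = dedup$question_id,
    discrepancies = disc,
    points = pts,
    normalized = pts / maxp
  )
}

#' Exam totals on the 20-point scale
#'
#' Each responder's total is `20 * sum(points) / sum(max_points)` over all
#' questions of the bank; the pass flag compares it to the pass mark (a
#' score exactly at the mark passes).
#'
#' @param graded Output of [grade_responses()].
#' @param bank A `question_bank` (defines the questions that must all be
#'   answered).
#' @param pass_mark Pass mark on the 20-point scale (default 10).
#' @return Tibble: `responder_id`, `responder_kind` (if present),
#'   `score_20`, `pass`.
#' @export
exam_score_20 <- function(graded, bank, pass_mark = 10) {
  qs <- bank$questions
  by_resp <- split(graded, graded$responder_id)
  out <- purrr::map_dfr(by_resp, function(g) {
    missing <- setdiff(qs$question_id, g$question_id)
    if (length(missing) > 0) {
      stop("responder ", g$responder_id[1], " is missing question(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    maxp <- qs$max_points[match(g$question_id, qs$question_id)]
    tibble::tibble(
      responder_id = g$responder_id[1],
      responder_kind = if ("responder_kind" %in% names(g)) g$responder_kind[1] else NA_character_,
      score_20 = 20 * sum(g$points) / sum(maxp)
    )
  })
  out$pass <- out$score_20 >= pass_mark
  out
}
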