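#' @title Domain model: questions, components, responses
#' @description
#' A question bank is a pair of tibbles: `questions` (one row per item, with
#' its option universe, answer key and maximum points) and `components` (one
#' row per docimological component — PCC, mPCC, KFP or IQS — with optional
#' author metadata). Multi-valued cells (option lists, keys, component
#' question lists) are "|"-separated strings of opaque, case-sensitive
#' labels.
#' @name exam_model
NULL

question_formats <- c("MCQ", "SBA", "EMQ", "SAQ")
component_types <- c("PCC", "mPCC", "KFP", "IQS")
author_specialties <- c("intensivist", "emergency")
author_ranks <- c("clinical_fellow", "associate_professor", "full_professor")
input_formats <- c("full_context", "sequential")

#' Construct and validate a question bank
#'
#' @param questions Tibble/data frame with columns `question_id`,
#'   `component_id`, `format` (one of MCQ, SBA, EMQ, SAQ), `options`
#'   ("|"-separated labels, empty for SAQ), `key` ("|"-separated subset of
#'   `options`, empty for SAQ) and optionally `max_points` (default 1).
#' @param components Tibble/data frame with columns `component_id`, `dtype`
#'   (PCC, mPCC, KFP, IQS) and optionally `question_ids`, `author_specialty`,
#'   `author_rank`, `cohort_label`. If `NULL`, components are derived from
#'   the questions with `dtype` `NA`.
#' @return A `question_bank` object (list with validated `questions` and
#'   `components` tibbles).
#' @examples
#' qs <- tibble::tibble(
#'   question_id = "q1", component_id = "c1", format = "MCQ",
#'   options = "A|B|C|D|E", key = "A|C", max_points = 1
#' )
#' question_bank(qs)
#' @export
question_bank <- function(questions, components = NULL) {
  questions <- tibble::as_tibble(questions)
  req <- c("question_id", "component_id", "format", "options", "key")
  miss <- setdiff(req, names(questions))
  if (length(miss) > 0) {
    stop("question table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"max_points" %in% names(questions)) questions$max_points <- 1
  questions$question_id <- as.character(questions$question_id)
  questions$component_id <- as.character(questions$component_id)
  questions$format <- as.character(questions$format)
  questions$options <- ifelse(is.na(questions$options), "", as.character(questions$options))
  questions$key <- ifelse(is.na(questions$key), "", as.character(questions$key))
  questions$max_points <- as.numeric(questions$max_points)
  questions <- questions[, c(req, "max_points")]

  if (is.null(components)) {
    components <- tibble::tibble(
      component_id = unique(questions$component_id),
      dtype = NA_character_
    )
  }
  components <- tibble::as_tibble(components)
  if (!"component_id" %in% names(components)) {
    stop("component table is missing column: component_id", call. = FALSE)
  }
  if (!"dtype" %in% names(components)) components$dtype <- NA_character_
  for (col in c("question_ids", "author_specialty", "author_rank", "cohort_label")) {
    if (!col %in% names(components)) components[[col]] <- NA_character_
  }
  components$component_id <- as.character(components$component_id)
  # derive per-component question lists where not given, in bank order
  derived <- vapply(
    components$component_id,
    function(cid) join_opts(questions$question_id[questions$component_id == cid]),
    character(1)
  )
  components$question_ids <- ifelse(
    is.na(components$question_ids) | !nzchar(components$question_ids),
    derived, as.character(components$question_ids)
  )
  components <- components[, c("component_id", "dtype", "question_ids",
                               "author_specialty", "author_rank", "cohort_label")]

  bank <- structure(list(questions = questions, components = components),
                    class = "question_bank")
  validate_question_bank(bank)
  bank
}

#' Validate question-bank invariants
#'
#' Checks, row by row: known formats; `key` a subset of `options`; MCQ-type
#' items have at least 2 options; SBA keys are singletons; SAQ items carry
#' neither options nor key; `max_points` positive; ids unique; every
#' component's `question_ids` exist, are non-empty and not duplicated.
#' Errors name the offending row.
#'
#' @param bank A `question_bank`.
#' @return The bank, invisibly, if valid.
#' @export
validate_question_bank <- function(bank) {
  q <- bank$questions
  if (anyDuplicated(q$question_id)) {
    stop("duplicate question_id: ",
         paste(unique(q$question_id[duplicated(q$question_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(q))) {
    id <- q$question_id[i]
    fmt <- q$format[i]
    opts <- split_opts(q$options[i])
    key <- split_opts(q$key[i])
    if (!fmt %in% question_formats) {
      stop("question ", id, ": unknown format '", fmt, "'", call. = FALSE)
    }
    if (anyDuplicated(opts)) {
      stop("question ", id, ": duplicated option labels", call. = FALSE)
    }
    if (!all(key %in% opts)) {
      stop("question ", id, ": key option(s) ",
           paste(setdiff(key, opts), collapse = ", "),
           " not in the option universe", call. = FALSE)
    }
    if (fmt == "SAQ") {
      if (length(opts) > 0 || length(key) > 0) {
        stop("question ", id, ": SAQ items have no options and no key",
             call. = FALSE)
      }
    } else {
      if (length(opts) < 2) {
        stop("question ", id, ": ", fmt, " items need at least 2 options",
             call. = FALSE)
      }
      if (fmt == "SBA" && length(key) != 1) {
        stop("question ", id, ": SBA items have exactly one key option",
             call. = FALSE)
      }
      if (length(key) < 1) {
        stop("question ", id, ": empty answer key", call. = FALSE)
      }
    }
    if (!is.finite(q$max_points[i]) || q$max_points[i] <= 0) {
      stop("question ", id, ": max_points must be positive", call. = FALSE)
    }
  }
  comp <- bank$components
  if (anyDuplicated(comp$component_id)) {
    stop("duplicate component_id", call. = FALSE)
  }
  bad_dtype <- !is.na(comp$dtype) & !comp$dtype %in% component_types
  if (any(bad_dtype)) {
    stop("component ", comp$component_id[which(bad_dtype)[1]],
         ": unknown dtype '", comp$dtype[which(bad_dtype)[1]], "'",
         call. = FALSE)
  }
  for (i in seq_len(nrow(comp))) {
    ids <- split_opts(comp$question_ids[i])
    if (length(ids) == 0) {
      stop("component ", comp$component_id[i], ": empty question list",
           call. = FALSE)
    }
    if (anyDuplicated(ids)) {
      stop("component ", comp$component_id[i], ": duplicated question ids",
           call. = FALSE)
    }
    if (!all(ids %in% q$question_id)) {
      stop("component ", comp$component_id[i], ": unknown question id(s) ",
           paste(setdiff(ids, q$question_id), collapse = ", "), call. = FALSE)
    }
  }
  orphan <- setdiff(q$component_id, comp$component_id)
  if (length(orphan) > 0) {
    stop("question(s) reference unknown component(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  invisible(bank)
}

#' @export
print.question_bank <- function(x, ...) {
  cat("<question_bank> ", nrow(x$questions), " questions in ",
      nrow(x$components), " components\n", sep = "")
  print(x$questions, ...)
  invisible(x)
}

#' Read a question bank from disk
#'
#' The `csv` dialect expects two files (questions and, optionally,
#' components); the `json` dialect one file with `questions` and
#' `components` arrays. Schemas are those documented in [question_bank()].
#'
#' @param path Questions CSV, or the JSON file.
#' @param components_path Components CSV (csv dialect only; optional).
#' @param dialect `"csv"` or `"json"`.
#' @return A validated `question_bank`.
#' @export
read_question_bank <- function(path, components_path = NULL,
                               dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    comp <- if (!is.null(raw$components) && NROW(raw$components) > 0) {
      tibble::as_tibble(raw$components)
    } else NULL
    return(question_bank(tibble::as_tibble(raw$questions), comp))
  }
  qs <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character(),
                                                      max_points = readr::col_double()),
                        na = "NA", progress = FALSE)
  comp <- if (!is.null(components_path)) {
    readr::read_csv(components_path,
                    col_types = readr::cols(.default = readr::col_character()),
                    na = "NA", progress = FALSE)
  } else NULL
  question_bank(qs, comp)
}

#' Write a question bank to disk
#'
#' @param bank A `question_bank`.
#' @param path Questions CSV path, or JSON path for the json dialect.
#' @param components_path Components CSV path (csv dialect).
#' @param dialect `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_question_bank <- function(bank, path, components_path = NULL,
                                dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    jsonlite::write_json(
      list(questions = bank$questions, components = bank$components),
      path, dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA
    )
    return(invisible(path))
  }
  readr::write_csv(bank$questions, path, na = "NA", progress = FALSE)
  if (!is.null(components_path)) {
    readr::write_csv(bank$components, components_path, na = "NA", progress = FALSE)
  }
  invisible(path)
}

#' Construct and validate a response table
#'
#' One row per responder x question. MCQ-type answers go in `selected`
#' ("|"-separated option labels; the empty string is an abstention);
#' pre-graded free-text answers go in `graded_points`. Exactly one of the
#' two must be populated per row. `ambiguity_report` is the responder's own
#' flag that the item is ambiguous and is only meaningful for model
#' responders; a student row with the flag set is rejected.
#'
#' @param responses Tibble/data frame with columns `responder_id`,
#'   `responder_kind` ("student"/"model"), `question_id`, and `selected` or
#'   `graded_points`; optional `answer_text`, `ambiguity_report`,
#'   `input_format`.
#' @return A validated tibble of class `response_table`.
#' @export
response_table <- function(responses) {
  r <- tibble::as_tibble(responses)
  req <- c("responder_id", "responder_kind", "question_id")
  miss <- setdiff(req, names(r))
  if (length(miss) > 0) {
    stop("response table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"selected" %in% names(r)) r$selected <- NA_character_
  if (!"graded_points" %in% names(r)) r$graded_points <- NA_real_
  if (!"answer_text" %in% names(r)) r$answer_text <- NA_character_
  if (!"ambiguity_report" %in% names(r)) r$ambiguity_report <- FALSE
  if (!"input_format" %in% names(r)) r$input_format <- NA_character_
  r$responder_id <- as.character(r$responder_id)
  r$responder_kind <- as.character(r$responder_kind)
  r$question_id <- as.character(r$question_id)
  r$selected <- as.character(r$selected)
  r$graded_points <- as.numeric(r$graded_points)
  r$answer_text <- as.character(r$answer_text)
  r$input_format <- as.character(r$input_format)
  r$ambiguity_report <- parse_flag(r$ambiguity_report)
  r <- r[, c(req, "selected", "graded_points", "answer_text",
             "ambiguity_report", "input_format")]

  bad_kind <- !r$responder_kind %in% c("student", "model")
  if (any(bad_kind)) {
    stop("row ", which(bad_kind)[1], ": unknown responder_kind '",
         r$responder_kind[which(bad_kind)[1]], "'", call. = FALSE)
  }
  both <- !is.na(r$selected) & !is.na(r$graded_points)
  if (any(both)) {
    stop("row ", which(both)[1], " (", r$responder_id[which(both)[1]], ", ",
         r$question_id[which(both)[1]],
         "): selected and graded_points are mutually exclusive", call. = FALSE)
  }
  neither <- is.na(r$selected) & is.na(r$graded_points)
  if (any(neither)) {
    stop("row ", which(neither)[1], " (", r$responder_id[which(neither)[1]], ", ",
         r$question_id[which(neither)[1]],
         "): one of selected / graded_points must be populated ",
         "(an empty selected string is a valid abstention)", call. = FALSE)
  }
  stud_flag <- r$responder_kind == "student" & r$ambiguity_report
  if (any(stud_flag)) {
    stop("row ", which(stud_flag)[1], " (", r$responder_id[which(stud_flag)[1]],
         "): ambiguity_report is reserved for model responders", call. = FALSE)
  }
  bad_fmt <- !is.na(r$input_format) & !r$input_format %in% input_formats
  if (any(bad_fmt)) {
    stop("row ", which(bad_fmt)[1], ": unknown input_format '",
         r$input_format[which(bad_fmt)[1]], "'", call. = FALSE)
  }
  class(r) <- c("response_table", class(r))
  r
}

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("1", "true", "t", "yes", "ambiguous=1")
  out
}

#' Read a response table from disk
#'
#' @param path CSV (columns as in [response_table()]; empty `selected`
#'   cells must be written as `""` or left empty with `graded_points` set)
#'   or JSON array of records.
#' @param dialect `"csv"` or `"json"`.
#' @return A validated `response_table` tibble.
#' @export
read_responses <- function(path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(response_table(tibble::as_tibble(raw)))
  }
  r <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character(),
                            graded_points = readr::col_double(),
                            ambiguity_report = readr::col_logical()),
    na = "NA", progress = FALSE
  )
  response_table(r)
}

#' Write a response table to disk
#'
#' @param responses A `response_table` (or coercible data frame).
#' @param path Output path.
#' @param dialect `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  responses <- response_table(responses)
  if (dialect == "json") {
    jsonlite::write_json(as.data.frame(responses), path, dataframe = "rows",
                         na = "null", auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(tibble::as_tibble(responses), path, na = "NA",
                     progress = FALSE)
  }
  invisible(path)
}

#' Detection thresholds and grading configuration
#'
#' Bundles every tunable the detector uses. Defaults are the canonical
#' values: tags fire on a mean normalized ensemble score strictly below
#' 0.5 with SD strictly below 0.3 (low performance), SD strictly above 0.3
#' (incoherence), at least 2 wrong models with at least 2 distinct wrong
#' answers (ambiguity), and at least 2 self-reports (subjective ambiguity).
#' Components scoring below 15/20 are flagged for review; the exam pass
#' mark is 10/20.
#'
#' @param low_perf_mean Mean-score threshold for the low-performance tag.
#' @param sd_split SD threshold separating low performance from incoherence.
#' @param min_wrong_models,min_distinct_wrong,min_ambiguity_reports
#'   "at least 2"-style counts for the ambiguity and subjective tags.
#' @param review_cutoff Component quality score (20-point scale) below
#'   which a component needs review.
#' @param pass_mark Exam pass mark on the 20-point scale.
#' @param incorrect_cutoff A model "failed to answer correctly" when its
#'   normalized score is strictly below this (default 1: any discrepancy).
#' @param sd_estimator `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @param rubric Partial-credit fractions of `max_points` indexed by
#'   discrepancy count starting at 0; counts beyond the vector score 0.
#' @param sba_all_or_nothing If `TRUE`, any wrong single-best-answer scores
#'   0 instead of the fractional rubric.
#' @param flat_tol Flatness tolerance for [elbow_threshold()], in
#'   min-max-normalized units.
#' @param restrict_input_format Optional `"full_context"` or
#'   `"sequential"`: score only records carrying that label.
#' @return A list of class `examaudit_thresholds`.
#' @export
thresholds <- function(low_perf_mean = 0.5,
                       sd_split = 0.3,
                       min_wrong_models = 2L,
                       min_distinct_wrong = 2L,
                       min_ambiguity_reports = 2L,
                       review_cutoff = 15,
                       pass_mark = 10,
                       incorrect_cutoff = 1,
                       sd_estimator = c("sample", "population"),
                       rubric = c(1, 0.5, 0.2),
                       sba_all_or_nothing = FALSE,
                       flat_tol = 0.02,
                       restrict_input_format = NULL) {
  sd_estimator <- match.arg(sd_estimator)
  th <- list(
    low_perf_mean = low_perf_mean, sd_split = sd_split,
    min_wrong_models = as.integer(min_wrong_models),
    min_distinct_wrong = as.integer(min_distinct_wrong),
    min_ambiguity_reports = as.integer(min_ambiguity_reports),
    review_cutoff = review_cutoff, pass_mark = pass_mark,
    incorrect_cutoff = incorrect_cutoff, sd_estimator = sd_estimator,
    rubric = as.numeric(rubric), sba_all_or_nothing = isTRUE(sba_all_or_nothing),
    flat_tol = flat_tol, restrict_input_format = restrict_input_format
  )
  stopifnot(
    th$low_perf_mean > 0, th$sd_split > 0, th$min_wrong_models >= 1,
    th$min_distinct_wrong >= 1, th$min_ambiguity_reports >= 1,
    th$min_distinct_wrong <= th$min_wrong_models,
    th$review_cutoff > 0, th$pass_mark > 0,
    all(th$rubric >= 0), all(th$rubric <= 1), th$flat_tol >= 0
  )
  structure(th, class = "examaudit_thresholds")
}

#' @rdname thresholds
#' @export
default_thresholds <- function() thresholds()

#' Read a thresholds block from a YAML or JSON config file
#'
#' The file holds a top-level `thresholds:` mapping (unknown keys are
#' rejected); missing keys take the defaults of [thresholds()].
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON config file.
#' @return An `examaudit_thresholds` list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  block <- cfg$thresholds %||% cfg
  known <- names(formals(thresholds))
  unknown <- setdiff(names(block), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(thresholds, block)
}

#' Write a component-quality report
#'
#' JSON and CSV are lossless round-trips of the quality table; markdown is
#' a human-readable report including band labels and review flags.
#'
#' @param results A component-quality tibble (see [component_quality()]).
#' @param path Output path.
#' @param format `"json"`, `"markdown"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "markdown", "csv")) {
  format <- match.arg(format)
  results <- tibble::as_tibble(results)
  if (format == "json") {
    jsonlite::write_json(as.data.frame(results), path, dataframe = "rows",
                         na = "null", auto_unbox = TRUE, digits = NA)
  } else if (format == "csv") {
    readr::write_csv(results, path, na = "NA", progress = FALSE)
  } else {
    lines <- c(
      "# Component quality report", "",
      paste0("| ", paste(names(results), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(results)), collapse = "|"), "|"),
      vapply(seq_len(nrow(results)), function(i) {
        paste0("| ", paste(vapply(results[i, ], function(v) {
          if (is.numeric(v)) format(round(v, 2), nsmall = 0) else as.character(v)
        }, character(1)), collapse = " | "), " |")
      }, character(1))
    )
    if ("needs_review" %in% names(results) && any(results$needs_review)) {
      lines <- c(lines, "",
                 paste0("Components needing review: ",
                        paste(results$component_id[results$needs_review],
                              collapse = ", ")))
    }
    writeLines(lines, path)
  }
  invisible(path)
}
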