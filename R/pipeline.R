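#' @title Pipeline orchestration and reporting
#' @name cli_report
NULL

#' Run the full audit pipeline
#'
#' grade -> per-question ensemble metrics -> tags -> component quality ->
#' group comparison (students vs models, when both kinds are present).
#' Stage errors abort with the stage name prefixed.
#'
#' @param bank A `question_bank`.
#' @param responses A `response_table` holding model (and optionally
#'   student) records.
#' @param config A [thresholds()] object.
#' @return A list of class `pipeline_run`: `config`, `graded`,
#'   `exam_scores`, `metrics`, `tags`, `quality`, `tag_combinations`,
#'   `comparison` (or `NULL`), `warnings`.
#' @export
run_pipeline <- function(bank, responses, config = default_thresholds()) {
  warnings <- character()
  stage <- function(name, expr) {
    tryCatch(
      withCallingHandlers(expr, warning = function(w) {
        warnings <<- c(warnings, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
      }
    )
  }
  responses <- response_table(responses)
  graded <- stage("grade", grade_responses(bank, responses, config))
  exam_scores <- stage("score", exam_score_20(graded, bank, config$pass_mark))
  metrics <- stage("metrics", summarize_questions(graded, responses, bank, config))
  tags <- stage("tag", assign_tags(metrics, config))
  quality <- stage("quality", component_quality(metrics, tags, bank, config))
  combos <- stage("tag", tag_combinations(tags))
  comparison <- NULL
  if (all(c("student", "model") %in% graded$responder_kind)) {
    comparison <- stage("compare", tryCatch(
      compare_samples(
        exam_scores$score_20[exam_scores$responder_kind == "student"],
        exam_scores$score_20[exam_scores$responder_kind == "model"],
        gate = "auto", labels = c("student", "model")
      ),
      error = function(e) {
        warnings <<- c(warnings, paste0("compare: ", conditionMessage(e)))
        NULL
      }
    ))
  }
  structure(
    list(config = config, graded = graded, exam_scores = exam_scores,
         metrics = metrics, tags = tags, quality = quality,
         tag_combinations = combos, comparison = comparison,
         warnings = warnings),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> ", nrow(x$metrics), " questions, ",
      nrow(x$quality), " components; ",
      sum(x$quality$needs_review), " flagged for review\n", sep = "")
  print(x$quality, ...)
  invisible(x)
}

#' Render a pipeline run as a report
#'
#' @param run A `pipeline_run`.
#' @param path Output path.
#' @param format `"json"` (machine-readable, stable key order — reruns on
#'   identical inputs are byte-identical) or `"markdown"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(run, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      questions = as.data.frame(
        dplyr::inner_join(run$metrics, run$tags, by = "question_id")),
      components = as.data.frame(run$quality),
      tag_combinations = as.data.frame(run$tag_combinations),
      comparison = if (!is.null(run$comparison)) {
        list(test_used = run$comparison$test_used,
             statistic = run$comparison$statistic,
             p_value = run$comparison$p_value,
             significant = run$comparison$significant)
      },
      warnings = run$warnings
    )
    jsonlite::write_json(payload, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  q <- dplyr::inner_join(run$metrics, run$tags, by = "question_id")
  lines <- c(
    "# Exam audit report", "",
    "## Per-question tags", "",
    sprintf("- %s: score %d (%s)", q$question_id, q$ambiguity_score, q$label),
    "", "## Component quality", "",
    sprintf("- %s [%s]: %.2f / 20 — %s%s",
            run$quality$component_id,
            ifelse(is.na(run$quality$dtype), "?", run$quality$dtype),
            run$quality$component_score, run$quality$band,
            ifelse(run$quality$needs_review, " (needs review)", "")),
    "", "## Tag combinations", "",
    sprintf("- %s: %d (%.1f%%)", run$tag_combinations$combination,
            run$tag_combinations$n, run$tag_combinations$percent)
  )
  if (!is.null(run$comparison)) {
    lines <- c(lines, "", "## Students vs models", "",
               sprintf("- %s, p = %.4g%s", run$comparison$test_used,
                       run$comparison$p_value,
                       if (run$comparison$significant) " (significant)" else ""))
  }
  if (length(run$warnings) > 0) {
    lines <- c(lines, "", "## Warnings", "", paste0("- ", run$warnings))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Planted-ambiguity recovery statistics
#'
#' Confusion of "ambiguity_score >= cutoff" against the simulator's ground
#' truth.
#'
#' @param tags Output of [assign_tags()].
#' @param truth Ground-truth tibble from [generate_bank()].
#' @param cutoff Flagging cutoff on the ambiguity score (default 2).
#' @return One-row tibble: `sensitivity`, `specificity`, `flagged_rate`,
#'   mean scores of planted and clean items, counts.
#' @export
recovery_stats <- function(tags, truth, cutoff = 2) {
  t2 <- dplyr::inner_join(tibble::as_tibble(tags), truth, by = "question_id")
  flagged <- t2$ambiguity_score >= cutoff
  pos <- t2$is_ambiguous
  tibble::tibble(
    n_planted = sum(pos),
    n_clean = sum(!pos),
    sensitivity = if (any(pos)) mean(flagged[pos]) else NA_real_,
    specificity = if (any(!pos)) mean(!flagged[!pos]) else NA_real_,
    flagged_rate = mean(flagged),
    mean_score_planted = if (any(pos)) mean(t2$ambiguity_score[pos]) else NA_real_,
    mean_score_clean = if (any(!pos)) mean(t2$ambiguity_score[!pos]) else NA_real_
  )
}
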