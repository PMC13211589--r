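#' @title Two-sample comparisons with a normality-gated test choice
#' @description
#' Score distributions (students vs models, or quality scores across author
#' groups) are compared with a Student two-tailed t test when both samples
#' pass a Shapiro-Wilk normality check at alpha 0.05, and a two-sided
#' Mann-Whitney U test otherwise. Significance is declared at P < .05.
#' @name cohort_stats
NULL

#' Descriptive statistics of a score vector
#'
#' Quartiles use the linear-interpolation convention (`stats::quantile`
#' type 7).
#'
#' @param scores Numeric vector (NAs dropped).
#' @return One-row tibble: `n`, `mean`, `sd`, `median`, `q1`, `q3`, `min`,
#'   `max`.
#' @export
describe <- function(scores) {
  x <- scores[!is.na(scores)]
  if (length(x) == 0) stop("no scores to describe", call. = FALSE)
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    n = length(x),
    mean = mean(x),
    sd = if (length(x) == 1) 0 else stats::sd(x),
    median = qs[2], q1 = qs[1], q3 = qs[3],
    min = min(x), max = max(x)
  )
}

shapiro_normal <- function(x, alpha = 0.05) {
  # Shapiro-Wilk is undefined for (near-)constant samples; treat those as
  # non-normal so the gate falls back to the rank test.
  if (length(unique(x)) < 3 || diff(range(x)) < .Machine$double.eps^0.5) {
    return(FALSE)
  }
  stats::shapiro.test(x)$p.value > alpha
}

#' Compare two score samples
#'
#' With `gate = "auto"` each sample is checked for normality with a
#' Shapiro-Wilk test at alpha 0.05; if both pass, a Student two-tailed
#' t test (equal variances) is used, otherwise a two-sided Mann-Whitney U
#' test. The Mann-Whitney p value is exact when both samples have at most
#' 8 observations and no ties occur; otherwise the normal approximation
#' with continuity and tie correction is used. A warning is emitted when
#' either sample has fewer than 5 observations (the comparison is fragile
#' but still computed).
#'
#' @param sample_a,sample_b Numeric vectors.
#' @param gate `"auto"`, `"force_mw"` or `"force_t"`.
#' @param labels Length-2 character vector naming the groups.
#' @param alpha Significance level (default 0.05).
#' @return A list of class `comparison_result`: `labels`, `n`,
#'   `test_used` ("t_test"/"mann_whitney"), `statistic`, `p_value`,
#'   `significant`, and a two-row `descriptives` tibble.
#' @export
compare_samples <- function(sample_a, sample_b,
                            gate = c("auto", "force_mw", "force_t"),
                            labels = c("a", "b"), alpha = 0.05) {
  gate <- match.arg(gate)
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (gate == "auto" && (length(a) < 3 || length(b) < 3)) {
    stop("auto gating needs at least 3 observations per group; ",
         "use gate = 'force_mw' or 'force_t'", call. = FALSE)
  }
  if (length(a) < 5 || length(b) < 5) {
    warning("fewer than 5 observations in a group; the comparison is fragile",
            call. = FALSE)
  }
  use_t <- switch(gate,
    force_t = TRUE,
    force_mw = FALSE,
    auto = shapiro_normal(a, alpha) && shapiro_normal(b, alpha)
  )
  if (use_t) {
    ht <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
    test_used <- "t_test"
  } else {
    exact <- length(a) <= 8 && length(b) <= 8 && !any(duplicated(c(a, b)))
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                         alternative = "two.sided")
    )
    test_used <- "mann_whitney"
  }
  res <- list(
    labels = labels,
    n = c(length(a), length(b)),
    test_used = test_used,
    statistic = unname(ht$statistic),
    p_value = unname(ht$p.value),
    significant = unname(ht$p.value) < alpha,
    descriptives = dplyr::bind_rows(
      dplyr::mutate(describe(a), group = labels[1], .before = 1),
      dplyr::mutate(describe(b), group = labels[2], .before = 1)
    )
  )
  class(res) <- "comparison_result"
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison> ", x$labels[1], " (n=", x$n[1], ") vs ", x$labels[2],
      " (n=", x$n[2], "): ", x$test_used, ", statistic = ",
      signif(x$statistic, 4), ", p = ", signif(x$p_value, 3),
      if (x$significant) " *" else "", "\n", sep = "")
  print(x$descriptives, ...)
  invisible(x)
}

#' Compare exam scores between groups of responders
#'
#' Splits a score table by a grouping column and runs [compare_samples()]
#' on each pair of groups.
#'
#' @param scores Tibble with a numeric `score` column (e.g. `score_20`
#'   from [exam_score_20()] renamed, or component quality scores) and the
#'   grouping column.
#' @param group Name of the grouping column.
#' @param value Name of the numeric column (default `"score_20"`).
#' @param gate Passed to [compare_samples()].
#' @return A list of `comparison_result`, one per group pair, named
#'   `"<a> vs <b>"`.
#' @export
compare_groups <- function(scores, group, value = "score_20",
                           gate = "auto") {
  scores <- tibble::as_tibble(scores)
  levels <- unique(scores[[group]])
  levels <- levels[!is.na(levels)]
  if (length(levels) < 2) stop("need at least 2 groups", call. = FALSE)
  pairs <- utils::combn(as.character(levels), 2, simplify = FALSE)
  out <- lapply(pairs, function(p) {
    compare_samples(scores[[value]][scores[[group]] == p[1]],
                    scores[[value]][scores[[group]] == p[2]],
                    gate = gate, labels = p)
  })
  names(out) <- vapply(pairs, function(p) paste(p, collapse = " vs "),
                       character(1))
  out
}
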