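# Small in-code fixtures shared across test files.

tiny_bank <- function() {
  question_bank(
    questions = tibble::tibble(
      question_id = c("q1", "q2", "q3"),
      component_id = "c1",
      format = c("MCQ", "SBA", "SAQ"),
      options = c("A|B|C|D|E", "A|B|C|D", ""),
      key = c("A|C", "B", ""),
      max_points = c(1, 1, 2)
    ),
    components = tibble::tibble(
      component_id = "c1", dtype = "IQS",
      author_specialty = "intensivist", author_rank = "clinical_fellow",
      cohort_label = "2024-M1"
    )
  )
}

# One model ensemble's responses to tiny_bank(), everything correct.
perfect_model_responses <- function(models = paste0("m", 1:4)) {
  response_table(tidyr::crossing(
    responder_id = models,
    tibble::tibble(question_id = c("q1", "q2", "q3"))
  ) |>
    dplyr::mutate(
      responder_kind = "model",
      selected = dplyr::case_match(question_id, "q1" ~ "A|C", "q2" ~ "B",
                                   .default = NA_character_),
      graded_points = ifelse(question_id == "q3", 2, NA_real_),
      ambiguity_report = FALSE
    ))
}

# Build a QuestionMetrics row directly (for tagging tests).
metrics_row <- function(question_id = "q", mean_score = 1, sd_score = 0,
                        n_incorrect = 0, n_distinct_wrong = 0,
                        n_ambiguity_reports = 0, n_models = 4) {
  tibble::tibble(question_id = question_id, mean_score = mean_score,
                 sd_score = sd_score, n_incorrect = n_incorrect,
                 n_distinct_wrong = n_distinct_wrong,
                 n_ambiguity_reports = n_ambiguity_reports,
                 n_models = n_models)
}

# Independent literal transcription of the four tag rules, kept deliberately
# separate from assign_tags() as its oracle.
oracle_tags <- function(m, th = default_thresholds()) {
  amb <- as.integer(m$n_incorrect >= th$min_wrong_models &&
                      m$n_distinct_wrong >= th$min_distinct_wrong)
  low <- as.integer(m$mean_score < th$low_perf_mean && m$sd_score < th$sd_split)
  inc <- as.integer(m$sd_score > th$sd_split)
  subj <- as.integer(m$n_ambiguity_reports >= th$min_ambiguity_reports)
  c(ambiguity = amb, low_performance = low, incoherence = inc,
    subjective_ambiguity = subj, ambiguity_score = amb + low + inc + subj)
}

# Random but internally consistent QuestionMetrics draws.
random_metrics <- function(n, seed) {
  set.seed(seed)
  n_models <- 4L
  n_incorrect <- sample(0:n_models, n, replace = TRUE)
  tibble::tibble(
    question_id = sprintf("r%04d", seq_len(n)),
    mean_score = round(stats::runif(n), 3),
    sd_score = round(stats::runif(n, 0, 0.6), 3),
    n_incorrect = n_incorrect,
    n_distinct_wrong = vapply(n_incorrect, function(k) sample(0:k, 1), integer(1)),
    n_ambiguity_reports = sample(0:n_models, n, replace = TRUE),
    n_models = n_models
  )
}

# Brute-force Mann-Whitney: exact two-sided p by enumerating all rank
# assignments of group A among the pooled sample (no ties).
brute_mw_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  all_u <- apply(utils::combn(length(pooled), na), 2, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  mu <- length(a) * length(b) / 2
  mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-9)
}

# Independent closed-form Student t (equal variances), p from pt().
brute_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(tstat), df = na + nb - 2)
}
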