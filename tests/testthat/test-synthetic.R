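small_cfg <- function(...) {
  base <- list(n_components = 2, questions_per_component = 10, n_students = 5,
               seed = 91)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

test_that("a fixed seed reproduces the dataset exactly", {
  d1 <- simulate_exam(small_cfg())
  d2 <- simulate_exam(small_cfg())
  expect_identical(d1$bank$questions, d2$bank$questions)
  expect_identical(d1$truth, d2$truth)
  expect_identical(as.data.frame(d1$students), as.data.frame(d2$students))
  expect_identical(as.data.frame(d1$models), as.data.frame(d2$models))
  d3 <- simulate_exam(small_cfg(seed = 92))
  expect_false(identical(as.data.frame(d1$models), as.data.frame(d3$models)))
})

test_that("zero prevalence plants no ambiguity", {
  g <- generate_bank(small_cfg(ambiguity_prevalence = 0))
  expect_false(any(g$truth$is_ambiguous))
  expect_true(all(g$truth$alt_keys == ""))
})

test_that("planted prevalence stays within binomial error", {
  cfg <- sim_config(n_components = 5, questions_per_component = 40,
                    ambiguity_prevalence = 0.3, seed = 14)
  g <- generate_bank(cfg)
  n <- nrow(g$truth)
  expect_equal(n, 200L)
  sd3 <- 3 * sqrt(n * 0.3 * 0.7)
  expect_lt(abs(sum(g$truth$is_ambiguous) - 0.3 * n), sd3)
})

test_that("alternative keys are valid, distinct readings", {
  g <- generate_bank(small_cfg(ambiguity_prevalence = 1, k_readings = 3))
  opts <- LETTERS[1:5]
  for (i in seq_len(nrow(g$truth))) {
    official <- sort(strsplit(g$truth$official_key[i], "|", fixed = TRUE)[[1]])
    alts <- lapply(strsplit(g$truth$alt_keys[i], ";", fixed = TRUE)[[1]],
                   function(s) sort(strsplit(s, "|", fixed = TRUE)[[1]]))
    expect_length(alts, 2)
    for (a in alts) {
      expect_true(all(a %in% opts))
      expect_gt(length(a), 0)
      expect_false(identical(a, official))
    }
    expect_false(identical(alts[[1]], alts[[2]]))
  }
})

test_that("generated data passes the domain validation", {
  d <- simulate_exam(small_cfg())
  expect_silent(validate_question_bank(d$bank))
  expect_s3_class(response_table(d$students), "response_table")
  expect_s3_class(response_table(d$models), "response_table")
  expect_false(any(d$students$ambiguity_report))
})

test_that("unbounded ability gives perfect students; an empty cohort is empty", {
  cfg <- small_cfg(ability_mean = 50, ability_sd = 0, ambiguity_prevalence = 0)
  d <- simulate_exam(cfg)
  g <- grade_responses(d$bank, d$students)
  expect_true(all(g$normalized == 1))
  empty <- simulate_students(d$bank, d$truth, small_cfg(n_students = 0))
  expect_equal(nrow(empty), 0L)
})

test_that("student mean score matches the toggle-model expectation", {
  # ability == difficulty: each of the 5 options toggles correctly w.p. 1/2,
  # so discrepancies ~ Binomial(5, 1/2) and the expected normalized score is
  # sum_k P(k) * rubric(k), computed here by brute-force expectation
  cfg <- sim_config(n_components = 1, questions_per_component = 30,
                    n_students = 120, ability_mean = 0, ability_sd = 0,
                    ambiguity_prevalence = 0, seed = 55)
  d <- simulate_exam(cfg)
  d$truth$difficulty <- 0
  students <- simulate_students(d$bank, d$truth, cfg)
  g <- grade_responses(d$bank, students)
  expected <- sum(stats::dbinom(0:5, 5, 0.5) * c(1, 0.5, 0.2, 0, 0, 0))
  mc_se <- sqrt(stats::var(g$normalized) / nrow(g))
  expect_lt(abs(mean(g$normalized) - expected), 5 * mc_se)
})

test_that("perfect competence on a clean bank scores 1 and tags nothing", {
  cfg <- small_cfg(competence = 1, ambiguity_prevalence = 0,
                   report_clean = 0, n_students = 0)
  d <- simulate_exam(cfg)
  g <- grade_responses(d$bank, d$models)
  expect_true(all(g$normalized == 1))
  m <- summarize_questions(g, d$models, d$bank)
  expect_true(all(assign_tags(m)$ambiguity_score == 0))
})

test_that("self-report rate on ambiguous items matches the binomial closed form", {
  # P(>= 2 reports), reports ~ Bin(4, 0.6): 1 - 0.4^4 - 4*0.6*0.4^3 = 0.8208
  cfg <- sim_config(n_components = 5, questions_per_component = 60,
                    ambiguity_prevalence = 1, report_ambiguous = 0.6,
                    n_students = 0, seed = 66)
  d <- simulate_exam(cfg)
  g <- grade_responses(d$bank, d$models)
  m <- summarize_questions(g, d$models, d$bank)
  rate <- mean(m$n_ambiguity_reports >= 2)
  p_closed <- 1 - stats::dbinom(0, 4, 0.6) - stats::dbinom(1, 4, 0.6)
  expect_equal(p_closed, 0.8208)
  mc_sd3 <- 3 * sqrt(p_closed * (1 - p_closed) / nrow(m))
  expect_lt(abs(rate - p_closed), mc_sd3)
})

test_that("distinct wrong answers on ambiguous items follow reading enumeration", {
  # K = 2, follow probability 0.5, perfect competence: all models answering
  # the alternative reading give the same (wrong) answer, so
  # n_distinct_wrong = 1 unless no model follows it (then 0). Expected
  # P(n_distinct_wrong == 1) = 1 - 0.5^4 by enumeration over 2^4 assignments.
  cfg <- sim_config(n_components = 4, questions_per_component = 50,
                    ambiguity_prevalence = 1, follow_alternative = 0.5,
                    competence = 1, report_ambiguous = 0, n_students = 0,
                    seed = 67)
  d <- simulate_exam(cfg)
  m <- summarize_questions(grade_responses(d$bank, d$models), d$models, d$bank)
  expect_true(all(m$n_distinct_wrong %in% c(0L, 1L)))
  # enumerate the 2^4 follow/not-follow assignments, each w.p. (1/2)^4:
  # at least one follower <=> exactly one distinct wrong answer
  assignments <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  p_one <- sum(apply(assignments, 1, any)) / 16
  expect_equal(p_one, 1 - 0.5^4)
  rate <- mean(m$n_distinct_wrong == 1)
  expect_lt(abs(rate - p_one), 3 * sqrt(p_one * (1 - p_one) / nrow(m)))
})

test_that("the detector recovers planted ambiguity at the strong-effect settings", {
  cfg <- sim_config(seed = 2026)  # 200 questions, 4 models, strong effect
  d <- simulate_exam(cfg)
  g <- grade_responses(d$bank, d$models)
  m <- summarize_questions(g, d$models, d$bank)
  tags <- assign_tags(m)
  rec <- recovery_stats(tags, d$truth, cutoff = 2)
  expect_gt(rec$mean_score_planted, rec$mean_score_clean)
  expect_gt(rec$sensitivity, 0.7)
  expect_gt(rec$specificity, 0.8)
})

test_that("a clean high-competence run rarely reaches the flagging cutoff", {
  cfg <- sim_config(seed = 2026, ambiguity_prevalence = 0, competence = 0.98,
                    n_students = 0)
  d <- simulate_exam(cfg)
  m <- summarize_questions(grade_responses(d$bank, d$models), d$models, d$bank)
  expect_lt(mean(assign_tags(m)$ambiguity_score >= 2), 0.05)
})
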