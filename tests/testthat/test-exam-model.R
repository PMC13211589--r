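test_that("question banks round-trip through csv and json", {
  bank <- tiny_bank()
  for (dialect in c("csv", "json")) {
    qp <- withr::local_tempfile(fileext = if (dialect == "csv") ".csv" else ".json")
    cp <- withr::local_tempfile(fileext = ".csv")
    if (dialect == "csv") {
      write_question_bank(bank, qp, cp, dialect = "csv")
      back <- read_question_bank(qp, cp, dialect = "csv")
    } else {
      write_question_bank(bank, qp, dialect = "json")
      back <- read_question_bank(qp, dialect = "json")
    }
    expect_equal(as.data.frame(back$questions), as.data.frame(bank$questions))
    expect_equal(as.data.frame(back$components), as.data.frame(bank$components))
  }
})

test_that("bank validation rejects schema and invariant violations", {
  qs <- tiny_bank()$questions

  bad_key <- qs; bad_key$key[1] <- "A|F"
  expect_error(question_bank(bad_key), "not in the option universe")

  dup <- rbind(qs, qs[1, ])
  expect_error(question_bank(dup), "duplicate question_id")

  one_opt <- qs; one_opt$options[1] <- "A"; one_opt$key[1] <- "A"
  expect_error(question_bank(one_opt), "at least 2 options")

  multi_sba <- qs; multi_sba$key[2] <- "A|B"
  expect_error(question_bank(multi_sba), "exactly one key")

  saq_opts <- qs; saq_opts$options[3] <- "A|B"
  expect_error(question_bank(saq_opts), "SAQ")

  neg <- qs; neg$max_points[1] <- -1
  expect_error(question_bank(neg), "max_points")

  expect_error(question_bank(qs[, -1]), "missing column")

  comp_bad <- tibble::tibble(component_id = "c1", dtype = "IQS",
                             question_ids = "q1|zzz")
  expect_error(question_bank(qs, comp_bad), "unknown question id")
})

test_that("randomized corruptions of a valid bank are all rejected", {
  base <- tiny_bank()$questions
  corruptions <- list(
    function(q) { q$key[1] <- "Z"; q },
    function(q) { q$question_id[2] <- q$question_id[1]; q },
    function(q) { q$format[1] <- "ESSAY"; q },
    function(q) { q$max_points[3] <- 0; q },
    function(q) { q$options[2] <- "A"; q },
    function(q) { q$key[3] <- "A"; q$options[3] <- "A|B"; q }
  )
  set.seed(7)
  for (i in 1:30) {
    corrupt <- sample(corruptions, 1)[[1]]
    expect_error(question_bank(corrupt(base)))
  }
})

test_that("response records parse, with abstention and flag semantics", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "responder_id,responder_kind,question_id,selected,graded_points,ambiguity_report",
    "gptX,model,q1,A|C,NA,TRUE",
    "gptY,model,q1,,NA,FALSE",
    "s1,student,q3,NA,1.5,FALSE"
  ), p)
  r <- read_responses(p)
  expect_equal(sort(split_opts <- strsplit(r$selected[1], "|", fixed = TRUE)[[1]]),
               c("A", "C"))
  expect_true(r$ambiguity_report[1])
  # empty selected cell is an abstention, not a missing answer
  expect_identical(r$selected[2], "")
  expect_equal(r$graded_points[3], 1.5)

  # abstention grades as |key| discrepancies
  g <- grade_responses(tiny_bank(), r[2, ])
  expect_equal(g$discrepancies, 2L)
  expect_equal(g$points, 0.2)
})

test_that("a student record carrying an ambiguity flag is rejected", {
  expect_error(
    response_table(tibble::tibble(
      responder_id = "s1", responder_kind = "student", question_id = "q1",
      selected = "A", ambiguity_report = TRUE
    )),
    "reserved for model responders"
  )
})

test_that("a record with both or neither answer field is rejected", {
  expect_error(response_table(tibble::tibble(
    responder_id = "m1", responder_kind = "model", question_id = "q1",
    selected = "A", graded_points = 0.5
  )), "mutually exclusive")
  expect_error(response_table(tibble::tibble(
    responder_id = "m1", responder_kind = "model", question_id = "q1",
    selected = NA_character_, graded_points = NA_real_
  )), "must be populated")
})

test_that("responses round-trip through csv and json", {
  r <- perfect_model_responses()
  for (dialect in c("csv", "json")) {
    p <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_responses(r, p, dialect = dialect)
    back <- read_responses(p, dialect = dialect)
    expect_equal(as.data.frame(back), as.data.frame(r))
  }
})

test_that("reports round-trip (json, csv) and markdown carries bands and flags", {
  quality <- tibble::tibble(
    component_id = c("c1", "c2"), dtype = c("IQS", "KFP"),
    n_questions = c(3L, 2L), component_score = c(16.67, 11.2),
    band = c("very_good", "poor"), needs_review = c(FALSE, TRUE)
  )
  pj <- withr::local_tempfile(fileext = ".json")
  write_report(quality, pj, "json")
  back <- tibble::as_tibble(jsonlite::read_json(pj, simplifyVector = TRUE))
  expect_equal(as.data.frame(back), as.data.frame(quality))

  pc <- withr::local_tempfile(fileext = ".csv")
  write_report(quality, pc, "csv")
  backc <- readr::read_csv(pc, show_col_types = FALSE)
  expect_equal(as.data.frame(backc), as.data.frame(quality))

  pm <- withr::local_tempfile(fileext = ".md")
  write_report(quality, pm, "markdown")
  md <- paste(readLines(pm), collapse = "\n")
  expect_match(md, "very_good")
  expect_match(md, "Components needing review: c2")
})

test_that("config files override defaults and reject unknown keys", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("thresholds:", "  sd_split: 0.25", "  pass_mark: 12"), p)
  cfg <- read_config(p)
  expect_equal(cfg$sd_split, 0.25)
  expect_equal(cfg$pass_mark, 12)
  expect_equal(cfg$low_perf_mean, 0.5)

  p2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("thresholds:", "  sd_splitt: 0.25"), p2)
  expect_error(read_config(p2), "unknown config key")
})

test_that("conflicting duplicate responses error; identical ones collapse", {
  bank <- tiny_bank()
  dup_same <- response_table(tibble::tibble(
    responder_id = "m1", responder_kind = "model",
    question_id = c("q1", "q1"), selected = c("A|C", "A|C"),
    input_format = c("full_context", "sequential")
  ))
  g <- grade_responses(bank, dup_same)
  expect_equal(nrow(g), 1L)

  dup_conflict <- response_table(tibble::tibble(
    responder_id = "m1", responder_kind = "model",
    question_id = c("q1", "q1"), selected = c("A|C", "A")
  ))
  expect_error(grade_responses(bank, dup_conflict), "conflicting duplicate")
})

test_that("input-format restriction drops the other format's records", {
  bank <- tiny_bank()
  r <- response_table(tibble::tibble(
    responder_id = "m1", responder_kind = "model",
    question_id = c("q1", "q1"), selected = c("A|C", "A"),
    input_format = c("full_context", "sequential")
  ))
  cfg <- thresholds(restrict_input_format = "full_context")
  g <- grade_responses(bank, r, cfg)
  expect_equal(nrow(g), 1L)
  expect_equal(g$discrepancies, 0L)
})
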