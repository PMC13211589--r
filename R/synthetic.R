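#' @title Synthetic exams with planted ambiguity
#' @description
#' End-to-end validation data for the detector: a question bank of
#' multi-select items, a student cohort answering under a logistic
#' ability-difficulty model, and a small model ensemble whose members
#' scatter across plausible answer keys on ambiguous items and self-report
#' ambiguity probabilistically. Ambiguity is *planted* as ground truth: an
#' ambiguous item admits `k_readings` plausible keys (the official key
#' plus alternatives differing by at least one option), and each model
#' independently commits to one reading before answering.
#' @name synthetic_exam
NULL

#' Simulation configuration
#'
#' Defaults describe a deliberately strong planted effect on a bank of
#' 200 multi-select questions answered by a 4-model ensemble: ambiguous
#' items (prevalence 0.3) admit 2 readings, a model follows the
#' alternative reading with probability 0.8, answers its chosen reading
#' with per-option competence 0.95, and self-reports ambiguity with
#' probability 0.6 on ambiguous items versus 0.05 on clean ones.
#'
#' @param n_components Number of docimological components.
#' @param questions_per_component Questions per component.
#' @param dtype_mix Component types to cycle through.
#' @param n_options Options per question.
#' @param key_size_range Inclusive range the answer-key size is drawn from.
#' @param n_students Student cohort size.
#' @param ability_mean,ability_sd Student ability distribution (logit scale).
#' @param ambiguity_noise Extra per-option toggle noise students suffer on
#'   ambiguous items (mixture weight toward a coin flip).
#' @param n_models Ensemble size.
#' @param competence Per-option probability that a model selects a key
#'   option / rejects a distractor of its chosen reading; scalar or one
#'   value per model.
#' @param ambiguity_prevalence Probability an item is planted ambiguous.
#' @param k_readings Number of plausible keys on an ambiguous item (>= 2).
#' @param follow_alternative Probability a model follows an alternative
#'   reading rather than the official key on an ambiguous item.
#' @param report_ambiguous,report_clean Self-report probabilities on
#'   ambiguous and clean items.
#' @param seed Root RNG seed; all stages draw from substreams derived from
#'   it, so a fixed seed reproduces the dataset exactly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_components = 5,
                       questions_per_component = 40,
                       dtype_mix = c("PCC", "mPCC", "KFP", "IQS"),
                       n_options = 5,
                       key_size_range = c(1, 3),
                       n_students = 80,
                       ability_mean = 1.5,
                       ability_sd = 1,
                       ambiguity_noise = 0.3,
                       n_models = 4,
                       competence = 0.95,
                       ambiguity_prevalence = 0.3,
                       k_readings = 2,
                       follow_alternative = 0.8,
                       report_ambiguous = 0.6,
                       report_clean = 0.05,
                       seed = 42) {
  cfg <- as.list(environment())
  probs <- c(cfg$competence, cfg$ambiguity_prevalence, cfg$follow_alternative,
             cfg$report_ambiguous, cfg$report_clean, cfg$ambiguity_noise)
  stopifnot(
    all(probs >= 0 & probs <= 1),
    cfg$k_readings >= 2,
    cfg$n_options >= 2,
    cfg$key_size_range[1] >= 1, cfg$key_size_range[2] < cfg$n_options,
    cfg$n_models >= 1,
    length(cfg$competence) %in% c(1L, cfg$n_models)
  )
  if (length(cfg$competence) == 1) {
    cfg$competence <- rep(cfg$competence, cfg$n_models)
  }
  structure(cfg, class = "sim_config")
}

# One alternative reading: flip membership of exactly two options, keeping
# the key non-empty. Two flips ensure a model committed to the alternative
# reading is unambiguously wrong under the official key (a single-option
# difference would leave a perfect alternative answer at exactly half
# credit with zero ensemble dispersion — a reading the performance-based
# tags cannot see by construction, which would defeat the planted effect).
alt_key <- function(key, options) {
  repeat {
    flip <- sample(options, 2)
    new <- union(setdiff(key, flip), setdiff(flip, key))
    if (length(new) > 0 && !setequal(new, key)) return(sort(new))
  }
}

#' Generate a synthetic question bank with planted ambiguity
#'
#' @param config A [sim_config()].
#' @return List with a validated `bank` (`question_bank`) and a `truth`
#'   tibble: `question_id`, `is_ambiguous`, `official_key`, `alt_keys`
#'   (";"-separated "|"-joined sets, empty for clean items) and the
#'   latent `difficulty` used by the student model.
#' @export
generate_bank <- function(config = sim_config()) {
  set.seed(substream_seed(config$seed, "bank"))
  n_q <- config$n_components * config$questions_per_component
  opts <- LETTERS[seq_len(config$n_options)]
  comp_ids <- sprintf("comp%02d", seq_len(config$n_components))
  dtypes <- rep_len(config$dtype_mix, config$n_components)

  qid <- sprintf("q%03d", seq_len(n_q))
  comp_of <- rep(comp_ids, each = config$questions_per_component)
  key_sizes <- sample(seq(config$key_size_range[1], config$key_size_range[2]),
                      n_q, replace = TRUE)
  keys <- lapply(key_sizes, function(k) sort(sample(opts, k)))
  is_amb <- stats::runif(n_q) < config$ambiguity_prevalence
  alt <- vapply(seq_len(n_q), function(i) {
    if (!is_amb[i]) return("")
    alts <- list()
    while (length(alts) < config$k_readings - 1) {
      cand <- alt_key(keys[[i]], opts)
      if (!any(vapply(alts, function(a) setequal(a, cand), logical(1)))) {
        alts <- c(alts, list(cand))
      }
    }
    paste(vapply(alts, join_opts, character(1)), collapse = ";")
  }, character(1))
  difficulty <- stats::rnorm(n_q, 0, 1)

  questions <- tibble::tibble(
    question_id = qid, component_id = comp_of, format = "MCQ",
    options = join_opts(opts),
    key = vapply(keys, join_opts, character(1)),
    max_points = 1
  )
  components <- tibble::tibble(
    component_id = comp_ids, dtype = dtypes,
    author_specialty = sample(author_specialties, config$n_components,
                              replace = TRUE),
    author_rank = sample(author_ranks, config$n_components, replace = TRUE),
    cohort_label = "synthetic"
  )
  truth <- tibble::tibble(
    question_id = qid, is_ambiguous = is_amb,
    official_key = questions$key, alt_keys = alt, difficulty = difficulty
  )
  list(bank = question_bank(questions, components), truth = truth)
}

# Answer a key with independent per-option toggles: each key option is
# selected with probability p, each distractor selected with 1 - p.
toggle_answer <- function(key, options, p_correct) {
  in_key <- options %in% key
  keep <- stats::runif(length(options)) < p_correct
  sel <- options[(in_key & keep) | (!in_key & !keep)]
  join_opts(sel)
}

#' Simulate a student cohort
#'
#' Student `s` answers question `q` by toggling each option correctly with
#' probability `plogis(ability_s - difficulty_q)`; on ambiguous items the
#' toggle probability is mixed toward a coin flip with weight
#' `ambiguity_noise`, modelling the confusion an ambiguous stem causes.
#'
#' @param bank A `question_bank` from [generate_bank()].
#' @param truth The matching ground-truth tibble.
#' @param config The [sim_config()] used to generate them.
#' @return A `response_table` of student records.
#' @export
simulate_students <- function(bank, truth, config = sim_config()) {
  if (config$n_students == 0) {
    return(response_table(tibble::tibble(
      responder_id = character(), responder_kind = character(),
      question_id = character(), selected = character()
    )))
  }
  set.seed(substream_seed(config$seed, "ability"))
  ability <- stats::rnorm(config$n_students, config$ability_mean,
                          config$ability_sd)
  sid <- sprintf("s%03d", seq_len(config$n_students))
  qs <- bank$questions
  rows <- purrr::map_dfr(seq_len(nrow(qs)), function(qi) {
    set.seed(substream_seed(config$seed, "students", qi))
    opts <- split_opts(qs$options[qi])
    key <- split_opts(qs$key[qi])
    p <- stats::plogis(ability - truth$difficulty[qi])
    if (truth$is_ambiguous[qi]) {
      p <- p * (1 - config$ambiguity_noise) + 0.5 * config$ambiguity_noise
    }
    tibble::tibble(
      responder_id = sid, responder_kind = "student",
      question_id = qs$question_id[qi],
      selected = vapply(p, function(pc) toggle_answer(key, opts, pc),
                        character(1))
    )
  })
  response_table(rows)
}

#' Simulate the model ensemble
#'
#' On a clean item every model answers the official key with its per-option
#' competence. On an ambiguous item each model first commits to one
#' reading — the official key with probability `1 - follow_alternative`,
#' otherwise one of the alternative keys uniformly — and then answers that
#' reading's key with its competence. Ambiguity self-reports fire with
#' probability `report_ambiguous` on planted items and `report_clean`
#' otherwise.
#'
#' @inheritParams simulate_students
#' @return A `response_table` of model records with `ambiguity_report`
#'   flags.
#' @export
simulate_models <- function(bank, truth, config = sim_config()) {
  qs <- bank$questions
  mid <- sprintf("model%d", seq_len(config$n_models))
  rows <- purrr::map_dfr(seq_len(nrow(qs)), function(qi) {
    set.seed(substream_seed(config$seed, "models", qi))
    opts <- split_opts(qs$options[qi])
    official <- split_opts(qs$key[qi])
    readings <- list(official)
    if (truth$is_ambiguous[qi] && nzchar(truth$alt_keys[qi])) {
      readings <- c(readings,
                    lapply(strsplit(truth$alt_keys[qi], ";", fixed = TRUE)[[1]],
                           split_opts))
    }
    ambiguous <- truth$is_ambiguous[qi]
    sel <- character(config$n_models)
    rep_flag <- logical(config$n_models)
    for (m in seq_len(config$n_models)) {
      reading <- if (ambiguous && length(readings) > 1 &&
                     stats::runif(1) < config$follow_alternative) {
        alts <- readings[-1]
        alts[[sample.int(length(alts), 1)]]
      } else {
        official
      }
      sel[m] <- toggle_answer(reading, opts, config$competence[m])
      p_rep <- if (ambiguous) config$report_ambiguous else config$report_clean
      rep_flag[m] <- stats::runif(1) < p_rep
    }
    tibble::tibble(
      responder_id = mid, responder_kind = "model",
      question_id = qs$question_id[qi], selected = sel,
      ambiguity_report = rep_flag
    )
  })
  response_table(rows)
}

#' Generate a complete synthetic exam dataset
#'
#' Convenience wrapper: bank + truth + student and model responses.
#'
#' @param config A [sim_config()].
#' @return List: `bank`, `truth`, `students`, `models`.
#' @export
simulate_exam <- function(config = sim_config()) {
  g <- generate_bank(config)
  list(
    bank = g$bank, truth = g$truth,
    students = simulate_students(g$bank, g$truth, config),
    models = simulate_models(g$bank, g$truth, config)
  )
}
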