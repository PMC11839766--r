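#' Lower median of a set of STAGES levels
#'
#' The stabilisation protocol repeats a stochastic classification and takes
#' the median outcome.  For even run counts the usual interpolated median can
#' fall off the half-step grid (e.g. 3.25), so the package uses the lower
#' median: the value at position `ceiling(n/2)` of the sorted runs.  The
#' result is always an attained grid value and is invariant to permuting the
#' runs.
#'
#' @param levels Non-empty numeric vector of STAGES levels (or category
#'   codes; any ordered numeric works).
#' @return The lower median, a scalar.
#' @examples
#' median_level(c(3.0, 3.0, 3.5))           # 3.0
#' median_level(c(3.0, 3.5))                # 3.0 (lower median)
#' @export
median_level <- function(levels) {
  if (length(levels) == 0) {
    abort_stagescore("`levels` must be non-empty.", "empty_input")
  }
  if (any(is.na(levels))) {
    abort_stagescore("`levels` must not contain missing values.", "invalid_value")
  }
  sort(levels)[ceiling(length(levels) / 2)]
}

#' Classify sentences with a backend and median-of-runs stabilisation
#'
#' For each sentence the backend answers the three classification questions
#' `n_runs` times.  Per-question lower medians and the lower median of the
#' per-run levels are recorded; the sentence's score is the median of the
#' per-run levels.  Ten runs is the protocol default: run-count calibration
#' (see [run_count_regression()]) shows the median outcome flattening by ten
#' runs for stochastic backends, and a deterministic backend collapses all
#' runs to one value.  A run whose reply cannot be parsed (condition class
#' `stagescore_unparsable_response`) is dropped with a warning; a sentence
#' needs at least one successful run per question.
#'
#' @param data A data frame with columns `id` and `text` (see
#'   [read_sentences()]); extra columns are carried through unchanged.
#' @param backend A backend object or bare function
#'   `(sentence, question_id) -> code`; see [stages_backend].
#' @param n_runs Number of classification runs per sentence; default 10.
#' @param seed Optional integer seed governing run ordering and any backend
#'   stub randomness.  Remote backends are nondeterministic regardless; their
#'   reproducibility boundary is the response cache.
#' @return A tibble with one row per sentence: the input columns plus
#'   `median_q1`, `median_q2`, `median_q3`, `median_level`, `n_runs`
#'   (successful runs), and a list-column `runs` holding the per-run tibble
#'   (`run`, `q1`, `q2`, `q3`, `level`).
#' @examples
#' sentences <- tibble::tibble(
#'   id = "s1", text = "The team won the game"
#' )
#' classify_sentences(sentences, backend_mock(), n_runs = 3)
#' @export
classify_sentences <- function(data, backend, n_runs = 10, seed = NULL) {
  if (!is.data.frame(data) || !all(c("id", "text") %in% names(data))) {
    abort_stagescore("`data` must be a data frame with columns `id` and `text`.",
                     "invalid_input")
  }
  if (length(n_runs) != 1 || is.na(n_runs) || n_runs < 1 || n_runs %% 1 != 0) {
    abort_stagescore("`n_runs` must be a positive integer.", "invalid_parameter")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  res <- purrr::map(seq_len(nrow(data)), function(i) {
    classify_one(data$id[[i]], data$text[[i]], backend, n_runs)
  })
  out <- as_tibble(data)
  out$median_q1 <- map_int(res, "median_q1")
  out$median_q2 <- map_int(res, "median_q2")
  out$median_q3 <- map_int(res, "median_q3")
  out$median_level <- map_dbl(res, "median_level")
  out$n_runs <- map_int(res, "n_runs")
  out$runs <- purrr::map(res, "runs")
  out
}

classify_one <- function(id, text, backend, n_runs) {
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    codes <- rep(NA_integer_, 3)
    for (q in 1:3) {
      codes[q] <- tryCatch(
        as.integer(backend_classify(backend, text, q)),
        stagescore_unparsable_response = function(e) {
          warning(sprintf("Sentence %s, run %d, question %d: %s (run dropped)",
                          id, r, q, conditionMessage(e)), call. = FALSE)
          NA_integer_
        }
      )
    }
    if (!anyNA(codes)) {
      runs[[r]] <- tibble(run = r, q1 = codes[1], q2 = codes[2], q3 = codes[3],
                          level = level_from_answers(codes[1], codes[2], codes[3]))
    }
  }
  runs <- dplyr::bind_rows(runs)
  if (nrow(runs) == 0) {
    abort_stagescore(
      sprintf("Sentence %s: all %d runs failed to produce a parsable triple.",
              id, n_runs),
      "classification_failed"
    )
  }
  list(
    median_q1 = as.integer(median_level(runs$q1)),
    median_q2 = as.integer(median_level(runs$q2)),
    median_q3 = as.integer(median_level(runs$q3)),
    median_level = median_level(runs$level),
    n_runs = nrow(runs),
    runs = runs
  )
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Aggregate sentence scores to a respondent-level score
#'
#' Positioning a respondent (or a group) on the STAGES scale uses the
#' arithmetic mean of their sentence scores rather than any single sentence,
#' snapped back to the half-step grid for reporting.  Subsample calibration
#' (see [subsample_stability()]) motivates the item-count defaults: ten
#' sentences is the recommended minimum and five the accepted floor.
#'
#' @param data A data frame with a `median_level` column (the output of
#'   [classify_sentences()]), or any data frame with a sentence-score column
#'   named by `level_col`.
#' @param min_sentences Minimum number of sentences required; default 5.
#' @param respondent Optional respondent identifier stored in the result.
#' @param level_col Name of the score column; default `"median_level"`.
#' @return A one-row tibble: `respondent`, `n_sentences`, `mean_level`,
#'   `snapped_level`.
#' @examples
#' scores <- tibble::tibble(median_level = c(3.0, 3.0, 3.5, 3.5, 4.0))
#' score_respondent(scores) # mean 3.4, snapped 3.5
#' @export
score_respondent <- function(data, min_sentences = 5, respondent = NA_character_,
                             level_col = "median_level") {
  if (!is.data.frame(data) || !level_col %in% names(data)) {
    abort_stagescore(
      sprintf("`data` must be a data frame with a `%s` column.", level_col),
      "invalid_input"
    )
  }
  levels <- data[[level_col]]
  if (nrow(data) < min_sentences) {
    abort_stagescore(
      sprintf("Respondent has %d sentences; at least %d are required.",
              nrow(data), min_sentences),
      "insufficient_items"
    )
  }
  if (!all(is_stages_level(levels))) {
    abort_stagescore("All sentence scores must lie on the STAGES grid.",
                     "invalid_level")
  }
  mean_level <- mean(levels)
  tibble(
    respondent = respondent,
    n_sentences = nrow(data),
    mean_level = mean_level,
    snapped_level = snap_to_grid(mean_level)
  )
}
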