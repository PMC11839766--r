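#' Run-count stabilisation regression
#'
#' How many classification runs are needed before the median outcome stops
#' drifting?  The calibration regresses the median outcome (per question and
#' for the aggregated level) on the run count over a family of windows that
#' share a common right endpoint: \[3, max\], \[5, max\], ..., \[20, max\]
#' by default, with `max = 30`.  A window whose slope is indistinguishable
#' from zero indicates that additional runs no longer move the median.
#'
#' @param medians A data frame in long form with columns `runs` (integer run
#'   count), `quantity` (e.g. `"q1"`, `"q2"`, `"q3"`, `"stage_level"`) and
#'   `median` (the median outcome at that run count).  Every run count from
#'   `min(window_starts)` to `max_runs` must be present for each quantity.
#' @param window_starts Integer vector of window left endpoints; default
#'   `c(3, 5, 10, 15, 20)`.
#' @param max_runs Common window right endpoint; default 30.
#' @return A tibble with columns `window_start`, `quantity`, `slope`,
#'   `intercept` (ordinary-least-squares fit of `median` on `runs` over the
#'   window).
#' @examples
#' med <- tibble::tibble(runs = 3:30, quantity = "stage_level",
#'                       median = 0.1 * (3:30) + 2)
#' run_count_regression(med)  # slope 0.1, intercept 2 for every window
#' @export
run_count_regression <- function(medians, window_starts = c(3, 5, 10, 15, 20),
                                 max_runs = 30) {
  if (!is.data.frame(medians) ||
      !all(c("runs", "quantity", "median") %in% names(medians))) {
    abort_stagescore(
      "`medians` must be a data frame with columns `runs`, `quantity`, `median`.",
      "invalid_input"
    )
  }
  if (any(window_starts < 3)) {
    abort_stagescore("Every window start must be at least 3.", "invalid_window")
  }
  quantities <- unique(medians$quantity)
  grids <- expand.grid(window_start = sort(window_starts),
                       quantity = quantities, stringsAsFactors = FALSE)
  rows <- purrr::map(seq_len(nrow(grids)), function(i) {
    ws <- grids$window_start[[i]]
    qt <- grids$quantity[[i]]
    sub <- medians[medians$quantity == qt &
                     medians$runs >= ws & medians$runs <= max_runs, ]
    if (nrow(sub) < 2) {
      abort_stagescore(
        sprintf("Window [%d, %d] for quantity `%s` has fewer than 2 points.",
                ws, max_runs, qt),
        "invalid_window"
      )
    }
    fit <- coef(lm(median ~ runs, data = sub))
    tibble(window_start = as.integer(ws), quantity = qt,
           slope = unname(fit[["runs"]]), intercept = unname(fit[["(Intercept)"]]))
  })
  purrr::list_rbind(rows)
}

#' Smallest stable run-count window
#'
#' Given the regression rows for the aggregated level, finds the smallest
#' window start from which every window at that start or later has
#' `|slope| <= slope_tolerance`.  If no such start exists the configured
#' maximum window start is returned with `stabilized = FALSE`; a flat-looking
#' early window followed by a sloped later one is not accepted, since the
#' drift has evidently not died out.
#'
#' @param rows Output of [run_count_regression()] (rows for other quantities
#'   are ignored).
#' @param slope_tolerance Absolute slope below which a window counts as flat.
#' @param quantity Which quantity's slopes to examine; default
#'   `"stage_level"`.
#' @return A one-row tibble: `window_start`, `stabilized` (logical).
#' @export
stabilization_point <- function(rows, slope_tolerance, quantity = "stage_level") {
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    abort_stagescore("`rows` must be a non-empty regression table.", "empty_input")
  }
  sub <- rows[rows$quantity == quantity, ]
  if (nrow(sub) == 0) {
    abort_stagescore(
      sprintf("No rows for quantity `%s`.", quantity), "empty_input"
    )
  }
  sub <- sub[order(sub$window_start), ]
  flat <- abs(sub$slope) <= slope_tolerance
  # all windows from the candidate onward must be flat
  ok <- rev(cumprod(rev(flat))) == 1
  if (any(ok)) {
    tibble(window_start = sub$window_start[which(ok)[1]], stabilized = TRUE)
  } else {
    tibble(window_start = max(sub$window_start), stabilized = FALSE)
  }
}

#' Subsample stability of the mean score
#'
#' How many items does a respondent need before the mean score is trustworthy?
#' For each candidate sample size the calibration draws `n_combos` random
#' combinations (without replacement within a combination) from the item
#' scores, measures `|combination mean - full-set mean|`, and reports the mean
#' and standard deviation (population form, divide by n) of those absolute
#' differences.  Both shrink toward zero as the sample size approaches the
#' full set, where they are exactly zero.
#'
#' @param scores Numeric vector of item scores (typically STAGES levels).
#' @param sizes Integer vector of subsample sizes to evaluate; default
#'   `2:(length(scores) - 1)`.
#' @param n_combos Number of random combinations per size; default 5000.
#'   Combinations may repeat across draws.
#' @param seed Optional integer seed.
#' @return A tibble with columns `sample_size`, `mean_abs_diff`,
#'   `sd_abs_diff`, `n_combos`.
#' @examples
#' subsample_stability(c(1, 2, 3), sizes = 2, n_combos = 100, seed = 1)
#' @export
subsample_stability <- function(scores, sizes = NULL, n_combos = 5000,
                                seed = NULL) {
  n <- length(scores)
  if (n < 2 || any(is.na(scores))) {
    abort_stagescore("`scores` must hold at least two non-missing values.",
                     "invalid_input")
  }
  sizes <- sizes %||% seq(2, n - 1)
  if (any(sizes < 2 | sizes > n | sizes %% 1 != 0)) {
    abort_stagescore(
      sprintf("Every size must be an integer in 2..%d.", n), "invalid_size"
    )
  }
  if (n_combos < 1) {
    abort_stagescore("`n_combos` must be at least 1.", "invalid_parameter")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  full_mean <- mean(scores)
  rows <- purrr::map(sizes, function(sz) {
    if (sz == n) {
      diffs <- rep(0, n_combos)
    } else {
      diffs <- vapply(seq_len(n_combos), function(i) {
        abs(mean(scores[sample.int(n, sz, replace = FALSE)]) - full_mean)
      }, numeric(1))
    }
    tibble(
      sample_size = as.integer(sz),
      mean_abs_diff = mean(diffs),
      sd_abs_diff = sqrt(mean((diffs - mean(diffs))^2)),
      n_combos = as.integer(n_combos)
    )
  })
  purrr::list_rbind(rows)
}
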