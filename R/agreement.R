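#' Cross-tabulate paired STAGES scores
#'
#' Builds the 12 x 12 ordinal contingency table of paired scores (rater A in
#' rows, rater B in columns).  The table is always indexed by the full fixed
#' grid, including categories no observation uses, so printed layouts are
#' comparable across datasets; weighted kappa is provably unaffected by the
#' empty padding.
#'
#' @param data A data frame holding the paired scores.
#' @param score_a,score_b Column names (strings) of the two raters' scores;
#'   defaults `"score_a"` and `"score_b"`.
#' @return An integer matrix of class `stages_crosstab` with the 12 grid
#'   labels as dimnames and attribute `n` (total count).
#' @examples
#' pairs <- tibble::tibble(score_a = c(4, 4, 3.5), score_b = c(4, 4.5, 4))
#' build_crosstab(pairs)
#' @export
build_crosstab <- function(data, score_a = "score_a", score_b = "score_b") {
  if (!is.data.frame(data) || !all(c(score_a, score_b) %in% names(data))) {
    abort_stagescore(
      sprintf("`data` must be a data frame with columns `%s` and `%s`.",
              score_a, score_b),
      "invalid_input"
    )
  }
  a <- data[[score_a]]
  b <- data[[score_b]]
  if (!all(is_stages_level(a)) || !all(is_stages_level(b))) {
    bad <- which(!is_stages_level(a) | !is_stages_level(b))
    abort_stagescore(
      sprintf("Off-grid score(s) in row(s) %s; scores must lie on the STAGES grid.",
              paste(head(bad, 5), collapse = ", ")),
      "invalid_level"
    )
  }
  grid <- stages_grid()
  labels <- format_level(grid)
  fa <- factor(format_level(a), levels = labels)
  fb <- factor(format_level(b), levels = labels)
  counts <- table(fa, fb)
  tab <- matrix(as.integer(counts), nrow = 12, ncol = 12,
                dimnames = list(rater_a = labels, rater_b = labels))
  structure(tab, n = sum(tab), class = c("stages_crosstab", class(tab)))
}

format_level <- function(x) {
  ifelse(x %% 1 == 0, sprintf("%d", as.integer(x)), sprintf("%.1f", x))
}

#' @export
print.stages_crosstab <- function(x, ...) {
  cat(sprintf("STAGES cross-tabulation (n = %d; rows rater A, cols rater B)\n",
              attr(x, "n")))
  print(unclass(x), ...)
  invisible(x)
}

#' Quadratic disagreement weights
#'
#' The weight matrix for ordinal agreement on a `k`-category scale:
#' `w[i, j] = (i - j)^2 / (k - 1)^2`.  Zero on the diagonal, 1 at the
#' opposite corners, symmetric; larger disagreements are penalised by the
#' squared category distance.
#'
#' @param k Number of ordered categories, at least 2.
#' @return A `k x k` numeric matrix.
#' @examples
#' quadratic_weights(2)
#' @export
quadratic_weights <- function(k) {
  if (length(k) != 1 || is.na(k) || k %% 1 != 0 || k < 2) {
    abort_stagescore("`k` must be an integer >= 2.", "invalid_dimension")
  }
  i <- matrix(seq_len(k), k, k)
  (i - t(i))^2 / (k - 1)^2
}

#' Quadratic-weighted Cohen's kappa with asymptotic standard error
#'
#' Chance-corrected agreement for two raters on an ordinal scale.  With
#' observed cell proportions `p[i, j]`, marginal proportions `r` and `c`, and
#' quadratic disagreement weights `w`,
#' \deqn{\kappa_w = 1 - \frac{\sum_{ij} w_{ij} p_{ij}}
#'                          {\sum_{ij} w_{ij} r_i c_j}.}
#' The standard error is the asymptotic non-null variance of
#' Fleiss, Cohen and Everitt, evaluated in the agreement-weight form
#' (`v = 1 - w`): with row/column mean agreement weights
#' `vbar_i. = sum_j v[i,j] c_j` and `vbar_.j = sum_i v[i,j] r_i`,
#' \deqn{\widehat{var}(\kappa_w) = \frac{\sum_{ij} p_{ij}\,[v_{ij} -
#'   (\bar v_{i.} + \bar v_{.j})(1 - \kappa_w)]^2 -
#'   [\kappa_w - p_e(1 - \kappa_w)]^2}{n (1 - p_e)^2}}
#' where `p_e` is the expected weighted agreement.  The 95% confidence
#' interval is `kappa +/- 1.96 * se`.
#'
#' @param tab A `stages_crosstab`, a plain square count matrix, or a data
#'   frame of score pairs (passed through [build_crosstab()]).
#' @param score_a,score_b Column names used when `tab` is a data frame.
#' @return An object of class `stages_kappa`: a list with elements `kappa`,
#'   `se`, `ci_low`, `ci_high`, `n`, `k` (number of categories) and
#'   `weights`.
#' @examples
#' pairs <- generate_paired_scores(n = 200, agreement = 0.8, seed = 1)
#' weighted_kappa(pairs)
#' @references Fleiss, J. L., Cohen, J., & Everitt, B. S. (1969). Large
#'   sample standard errors of kappa and weighted kappa. Psychological
#'   Bulletin, 72(5), 323-327.
#' @export
weighted_kappa <- function(tab, score_a = "score_a", score_b = "score_b") {
  if (is.data.frame(tab)) {
    tab <- build_crosstab(tab, score_a = score_a, score_b = score_b)
  }
  if (!is.matrix(tab) || nrow(tab) != ncol(tab)) {
    abort_stagescore("`tab` must be a square count matrix or a pairs data frame.",
                     "invalid_input")
  }
  mode(tab) <- "numeric"
  if (any(tab < 0) || any(!is.finite(tab))) {
    abort_stagescore("Counts must be finite and non-negative.", "invalid_input")
  }
  n <- sum(tab)
  k <- nrow(tab)
  if (n < 2) {
    abort_stagescore("The table must hold at least two observations.",
                     "invalid_input")
  }
  p <- tab / n
  r <- rowSums(p)
  cc <- colSums(p)
  if (sum(r > 0 | cc > 0) < 2) {
    abort_stagescore("At least two distinct categories must be observed.",
                     "degenerate_table")
  }
  w <- quadratic_weights(k)
  expected_disagreement <- sum(w * outer(r, cc))
  if (expected_disagreement <= 0) {
    abort_stagescore(
      "Zero expected disagreement: all mass in one category for both raters.",
      "degenerate_table"
    )
  }
  kappa <- 1 - sum(w * p) / expected_disagreement
  # variance in the agreement-weight form v = 1 - w
  v <- 1 - w
  pe <- sum(v * outer(r, cc))
  vbar_row <- as.vector(v %*% cc)   # sum_j v[i,j] c_j
  vbar_col <- as.vector(r %*% v)    # sum_i v[i,j] r_i
  term <- sum(p * (v - outer(vbar_row, vbar_col, `+`) * (1 - kappa))^2)
  var_kappa <- (term - (kappa - pe * (1 - kappa))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(var_kappa, 0))
  structure(
    list(kappa = kappa, se = se,
         ci_low = kappa - 1.96 * se, ci_high = kappa + 1.96 * se,
         n = as.integer(n), k = as.integer(k), weights = "quadratic"),
    class = "stages_kappa"
  )
}

#' @export
print.stages_kappa <- function(x, ...) {
  cat("Weighted Cohen's kappa (quadratic weights)\n")
  cat(sprintf("  kappa  = %.5f\n  se     = %.5f\n  95%% CI = [%.5f, %.5f]\n  n      = %d\n",
              x$kappa, x$se, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' @rdname weighted_kappa
#' @param x A `stages_kappa` object.
#' @param ... Unused.
#' @method tidy stages_kappa
#' @export
tidy.stages_kappa <- function(x, ...) {
  tibble(
    term = "weighted kappa",
    estimate = x$kappa,
    std.error = x$se,
    conf.low = x$ci_low,
    conf.high = x$ci_high
  )
}

#' @rdname weighted_kappa
#' @method glance stages_kappa
#' @export
glance.stages_kappa <- function(x, ...) {
  tibble(kappa = x$kappa, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
         n = x$n, k = x$k, weights = x$weights)
}

#' Aggregate agreement over resampled item subsets
#'
#' Measures how well two raters agree on *averaged* scores rather than single
#' items: draws `n_combos` random combinations of `combo_size` pairs (without
#' replacement within a combination), computes each rater's mean over the
#' combination, snaps both means to the half-step grid, and computes
#' [weighted_kappa()] over the resampled snapped mean-pairs.  Combinations
#' may repeat across draws.
#'
#' Note the resampled mean-pairs overlap in their underlying items, so they
#' are not independent observations; the asymptotic standard error attached
#' to the aggregate kappa is descriptive, not inferential.
#'
#' @inheritParams build_crosstab
#' @param combo_size Number of items averaged per combination; default 10.
#' @param n_combos Number of random combinations; default 5000.
#' @param seed Optional integer seed for the combination draws.
#' @return A `stages_kappa` object with extra fields `combo_size` and
#'   `n_combos`; the resampled snapped mean-pairs are attached as the
#'   tibble attribute `"means"`.
#' @examples
#' pairs <- load_fixture("table3")
#' aggregate_agreement(pairs, score_a = "map_score", score_b = "stages_score",
#'                     combo_size = 10, n_combos = 200, seed = 1)
#' @export
aggregate_agreement <- function(data, combo_size = 10, n_combos = 5000,
                                seed = NULL, score_a = "score_a",
                                score_b = "score_b") {
  if (!is.data.frame(data) || !all(c(score_a, score_b) %in% names(data))) {
    abort_stagescore(
      sprintf("`data` must be a data frame with columns `%s` and `%s`.",
              score_a, score_b),
      "invalid_input"
    )
  }
  n <- nrow(data)
  if (combo_size < 1 || combo_size > n || combo_size %% 1 != 0) {
    abort_stagescore(
      sprintf("`combo_size` must be an integer in 1..%d.", n), "invalid_size"
    )
  }
  if (n_combos < 1) {
    abort_stagescore("`n_combos` must be at least 1.", "invalid_parameter")
  }
  a <- data[[score_a]]
  b <- data[[score_b]]
  if (!all(is_stages_level(a)) || !all(is_stages_level(b))) {
    abort_stagescore("All scores must lie on the STAGES grid.", "invalid_level")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  mean_a <- numeric(n_combos)
  mean_b <- numeric(n_combos)
  for (i in seq_len(n_combos)) {
    idx <- sample.int(n, combo_size, replace = FALSE)
    mean_a[i] <- mean(a[idx])
    mean_b[i] <- mean(b[idx])
  }
  means <- tibble(score_a = snap_to_grid(mean_a), score_b = snap_to_grid(mean_b))
  out <- weighted_kappa(means)
  out$combo_size <- as.integer(combo_size)
  out$n_combos <- as.integer(n_combos)
  attr(out, "means") <- means
  out
}
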