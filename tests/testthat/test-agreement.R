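test_that("quadratic weights are symmetric, zero-diagonal, corner-maximal", {
  expect_equal(quadratic_weights(2), matrix(c(0, 1, 1, 0), 2))
  w <- quadratic_weights(12)
  expect_equal(w[1, 12], 1)
  expect_equal(w[12, 1], 1)
  expect_true(all(diag(w) == 0))
  expect_equal(w, t(w))
  expect_error(quadratic_weights(1), class = "stagescore_invalid_dimension")
})

test_that("the fixture cross-tabulation reproduces the reference table cell-for-cell", {
  fx <- load_fixture("table3")
  tab <- build_crosstab(fx, score_a = "map_score", score_b = "stages_score")
  expect_equal(unclass(tab)[, ], reference_crosstab()[, ])
  expect_equal(attr(tab, "n"), 58L)
})

test_that("crosstab handles empty input, diagonal pairs and off-grid values", {
  empty <- build_crosstab(tibble::tibble(score_a = numeric(), score_b = numeric()))
  expect_equal(sum(empty), 0L)
  expect_equal(dim(empty), c(12L, 12L))

  diag_pairs <- tibble::tibble(score_a = c(2, 3.5, 6), score_b = c(2, 3.5, 6))
  dtab <- build_crosstab(diag_pairs)
  expect_equal(sum(dtab), sum(diag(dtab)))

  expect_error(build_crosstab(tibble::tibble(score_a = 4.2, score_b = 4)),
               class = "stagescore_invalid_level")
})

test_that("weighted kappa and its asymptotic se match the published validation values", {
  fx <- load_fixture("table3")
  res <- weighted_kappa(fx, score_a = "map_score", score_b = "stages_score")
  expect_equal(res$kappa, 0.77987, tolerance = 5e-5 / 0.78)
  expect_equal(res$se, 0.05491, tolerance = 5e-4 / 0.055)
  expect_equal(res$ci_low, res$kappa - 1.96 * res$se)
  expect_equal(res$ci_high, res$kappa + 1.96 * res$se)
  expect_equal(res$n, 58L)
})

test_that("weighted kappa matches an independent oracle on a 5x5 table", {
  tab <- rbind(
    c(8, 2, 0, 1, 0),
    c(3, 10, 2, 0, 0),
    c(0, 4, 12, 3, 1),
    c(1, 0, 2, 9, 2),
    c(0, 0, 1, 3, 6)
  )
  res <- weighted_kappa(tab)
  # reference values from an independent large-sample kappa implementation
  expect_equal(res$kappa, 0.7942978617, tolerance = 1e-9)
  expect_equal(res$se, 0.0611329025, tolerance = 1e-8)
})

test_that("kappa is 1 on diagonal tables and 0 on marginal-product tables", {
  d <- diag(c(5, 0, 3, 2, 0, 0, 1, 4, 0, 2, 0, 1))
  expect_equal(weighted_kappa(d)$kappa, 1.0)

  r <- c(4, 0, 2, 0, 1, 3, 0, 0, 2, 0, 0, 0)
  cc <- c(0, 2, 1, 0, 3, 0, 4, 0, 0, 1, 0, 1)
  prod_tab <- outer(r, cc)  # counts proportional to the marginal product
  expect_equal(weighted_kappa(prod_tab)$kappa, 0, tolerance = 1e-12)
})

test_that("kappa lies in [-1, 1] and equals 1 only for purely diagonal tables", {
  set.seed(53)
  for (i in 1:25) {
    tab <- matrix(rpois(144, 1.2), 12, 12)
    if (sum(tab) < 2) next
    res <- try(weighted_kappa(tab), silent = TRUE)
    if (inherits(res, "try-error")) next
    expect_gte(res$kappa, -1)
    expect_lte(res$kappa, 1)
    if (res$kappa == 1) expect_equal(sum(tab) - sum(diag(tab)), 0)
  }
})

test_that("kappa is invariant to weight rescaling and empty-category padding", {
  set.seed(57)
  pairs <- generate_paired_scores(300, agreement = 0.6, seed = 57)
  tab <- build_crosstab(pairs)
  res <- weighted_kappa(tab)

  # manual kappa with unnormalised weights (i - j)^2: the (k-1)^2 factor
  # cancels between observed and expected disagreement
  p <- unclass(tab) / sum(tab)
  w <- outer(1:12, 1:12, function(i, j) (i - j)^2)
  kappa_unnorm <- 1 - sum(w * p) / sum(w * outer(rowSums(p), colSums(p)))
  expect_equal(res$kappa, kappa_unnorm, tolerance = 1e-12)

  # padding with unused flanking categories preserves spacing, hence kappa
  # and se
  padded <- matrix(0, 16, 16)
  padded[3:14, 3:14] <- unclass(tab)
  res_padded <- weighted_kappa(padded)
  expect_equal(res_padded$kappa, res$kappa, tolerance = 1e-12)
  expect_equal(res_padded$se, res$se, tolerance = 1e-12)
})

test_that("degenerate tables are rejected", {
  one_cell <- matrix(0, 12, 12); one_cell[4, 4] <- 30
  expect_error(weighted_kappa(one_cell), class = "stagescore_degenerate_table")
  expect_error(weighted_kappa(matrix(c(1, 0, 0, 0), 2)),
               class = "stagescore_invalid_input")
})

test_that("tidy and glance expose the fit in broom conventions", {
  res <- weighted_kappa(load_fixture("table3"),
                        score_a = "map_score", score_b = "stages_score")
  td <- tidy(res)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_equal(td$estimate, res$kappa)
  gl <- glance(res)
  expect_equal(gl$n, 58L)
  expect_equal(gl$weights, "quadratic")
})

test_that("aggregate agreement is exact for perfect raters and approaches the
           per-sentence kappa for single-item combinations", {
  agree <- tibble::tibble(score_a = rep(stages_grid(), 3),
                          score_b = rep(stages_grid(), 3))
  res <- aggregate_agreement(agree, combo_size = 4, n_combos = 300, seed = 1)
  expect_equal(res$kappa, 1.0)

  fx <- load_fixture("table3")
  single <- aggregate_agreement(fx, combo_size = 1, n_combos = 20000, seed = 2,
                                score_a = "map_score", score_b = "stages_score")
  per_sentence <- weighted_kappa(fx, score_a = "map_score",
                                 score_b = "stages_score")
  expect_equal(single$kappa, per_sentence$kappa, tolerance = 0.05)
})

test_that("aggregate agreement validates sizes and is seed-reproducible", {
  fx <- load_fixture("table3")
  expect_error(
    aggregate_agreement(fx, combo_size = 59, score_a = "map_score",
                        score_b = "stages_score"),
    class = "stagescore_invalid_size"
  )
  a <- aggregate_agreement(fx, combo_size = 10, n_combos = 200, seed = 7,
                           score_a = "map_score", score_b = "stages_score")
  b <- aggregate_agreement(fx, combo_size = 10, n_combos = 200, seed = 7,
                           score_a = "map_score", score_b = "stages_score")
  expect_equal(a$kappa, b$kappa)
  expect_equal(attr(a, "means"), attr(b, "means"))
  expect_true(all(is_stages_level(attr(a, "means")$score_a)))
})
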