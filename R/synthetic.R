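#' Generate paired ordinal scores with a known agreement level
#'
#' Draws score pairs from a copy-mixture model: rater A is drawn from
#' `marginal`; with probability `agreement` rater B copies A, otherwise B is
#' an independent draw from the same marginal.  Under this model the
#' population quadratic-weighted kappa equals `agreement` for *any* marginal
#' (observed weighted disagreement is `(1 - a)` times the chance-expected
#' disagreement), which makes the generator an analytic oracle for
#' [weighted_kappa()] parameter-recovery tests.
#'
#' @param n Number of pairs.
#' @param agreement Copy probability `a` in \[0, 1\]; the population
#'   quadratic-weighted kappa.
#' @param marginal Probability vector over the 12 grid levels; default
#'   uniform.
#' @param seed Optional integer seed.
#' @return A tibble with columns `score_a`, `score_b`.
#' @examples
#' pairs <- generate_paired_scores(n = 1000, agreement = 0.8, seed = 1)
#' weighted_kappa(pairs)$kappa  # close to 0.8
#' @export
generate_paired_scores <- function(n, agreement, marginal = NULL, seed = NULL) {
  grid <- stages_grid()
  marginal <- marginal %||% rep(1 / 12, 12)
  if (length(marginal) != 12 || any(marginal < 0) ||
      abs(sum(marginal) - 1) > 1e-8) {
    abort_stagescore(
      "`marginal` must be a length-12 probability vector over the grid.",
      "invalid_spec"
    )
  }
  if (length(agreement) != 1 || is.na(agreement) || agreement < 0 ||
      agreement > 1) {
    abort_stagescore("`agreement` must lie in [0, 1].", "invalid_spec")
  }
  if (n < 0 || n %% 1 != 0) {
    abort_stagescore("`n` must be a non-negative integer.", "invalid_spec")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  a <- sample(grid, n, replace = TRUE, prob = marginal)
  b <- sample(grid, n, replace = TRUE, prob = marginal)
  copy <- runif(n) < agreement
  b[copy] <- a[copy]
  tibble(score_a = a, score_b = b)
}

# template vocabulary locked to the mock backend's marker rules, so that
# mock_classify() recovers the intended triple by construction
sentence_templates <- list(
  subject_individual = c("She", "He", "The child", "The student"),
  subject_collective = c("The team", "The community", "The group",
                         "The family"),
  verb_active = c("builds", "paints", "organizes", "creates"),
  verb_passive = c("is given", "was shown", "is offered", "was handed"),
  object_concrete = c("the red car", "a wooden chair", "the old bicycle",
                      "a warm meal"),
  object_subtle = c("a sense of balance", "a belief in fairness",
                    "a vision of future possibilities",
                    "a set of guiding values"),
  object_metaware = c("an awareness of the moment",
                      "the construct of experience",
                      "a perception of consciousness",
                      "an insight into the nature of reality")
)

#' Generate marker-bearing synthetic sentences with known levels
#'
#' Assembles sentences from a subject / verb / object template vocabulary
#' whose words carry exactly the markers the mock backend keys on: the
#' subject encodes the Individual/Collective answer, the verb form the
#' Passive/Active answer, and the object the Concrete/Subtle/MetAware tier.
#' [mock_classify()] therefore recovers the intended answer triple — and the
#' pipeline the intended level — for every generated sentence.  These
#' sentences exercise the machinery end to end with known ground truth; they
#' are deliberately *not* a simulation of human sentence-completion-test
#' responses.
#'
#' @param n Number of sentences.
#' @param level_distribution Probability vector over the 12 grid levels;
#'   default uniform.
#' @param seed Optional integer seed.
#' @return A tibble with columns `id`, `text`, `q1`, `q2`, `q3` (intended
#'   answers) and `level` (intended STAGES level).
#' @examples
#' s <- generate_sentences(3, seed = 1)
#' s$text
#' @export
generate_sentences <- function(n, level_distribution = NULL, seed = NULL) {
  level_distribution <- level_distribution %||% rep(1 / 12, 12)
  if (length(level_distribution) != 12 || any(level_distribution < 0) ||
      abs(sum(level_distribution) - 1) > 1e-8) {
    abort_stagescore(
      "`level_distribution` must be a length-12 probability vector.",
      "invalid_spec"
    )
  }
  if (n < 0 || n %% 1 != 0) {
    abort_stagescore("`n` must be a non-negative integer.", "invalid_spec")
  }
  if (n == 0) {
    return(tibble(id = character(), text = character(), q1 = integer(),
                  q2 = integer(), q3 = integer(), level = numeric()))
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  levels <- sample(stages_grid(), n, replace = TRUE, prob = level_distribution)
  answers <- answers_from_level(levels)
  tpl <- sentence_templates
  pick <- function(x, size) x[sample.int(length(x), size, replace = TRUE)]
  subject <- ifelse(answers$q2 == 1,
                    pick(tpl$subject_individual, n),
                    pick(tpl$subject_collective, n))
  verb <- ifelse(answers$q3 == 2,
                 pick(tpl$verb_active, n),
                 pick(tpl$verb_passive, n))
  object <- character(n)
  object[answers$q1 == 1] <- pick(tpl$object_concrete, sum(answers$q1 == 1))
  object[answers$q1 == 2] <- pick(tpl$object_subtle, sum(answers$q1 == 2))
  object[answers$q1 == 3] <- pick(tpl$object_metaware, sum(answers$q1 == 3))
  tibble(
    id = sprintf("syn-%d", seq_len(n)),
    text = paste0(subject, " ", verb, " ", object, "."),
    q1 = answers$q1, q2 = answers$q2, q3 = answers$q3,
    level = levels
  )
}
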