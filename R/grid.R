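#' The STAGES level grid
#'
#' The STAGES model places every sentence on a 12-level ordinal scale running
#' from 1.0 to 6.5 in half steps.  The twelve levels arise from three crossed
#' dimensions: the tier of object awareness (Concrete, Subtle, MetAware), the
#' person perspective (Individual, Collective) and the agency orientation
#' (Passive, Active).  Each tier spans a block of four half-step levels;
#' moving from Individual to Collective adds a whole step within the block and
#' moving from Passive to Active adds a half step.
#'
#' @return A strictly increasing numeric vector of the 12 grid values
#'   `1.0, 1.5, ..., 6.5`.
#' @examples
#' stages_grid()
#' @export
stages_grid <- function() {
  seq(1, 6.5, by = 0.5)
}

#' Test whether values lie on the STAGES grid
#'
#' @param x Numeric vector.
#' @return Logical vector, `TRUE` where `x` is one of the 12 half-step levels.
#' @examples
#' is_stages_level(c(3.5, 4.2, NA))
#' @export
is_stages_level <- function(x) {
  !is.na(x) & is.finite(x) & (x * 2) %% 1 == 0 & x >= 1 & x <= 6.5
}

#' Map the three classification answers to a STAGES level
#'
#' The scoring protocol answers three questions about a sentence and combines
#' the categorical answers into one of the 12 levels:
#' \describe{
#'   \item{q1}{tier of object awareness: 1 = Concrete, 2 = Subtle,
#'     3 = MetAware}
#'   \item{q2}{person perspective: 1 = Individual, 2 = Collective}
#'   \item{q3}{agency: 1 = Passive, 2 = Active}
#' }
#' The decision tree is equivalent to the closed form
#' `2 * (q1 - 1) + q2 + 0.5 * (q3 - 1)`: each tier owns a block of four
#' consecutive half-step levels (Concrete 1.0-2.5, Subtle 3.0-4.5, MetAware
#' 5.0-6.5), the Collective focus adds a whole step within the block and the
#' Active orientation adds a half step.  The map is a bijection between the
#' 12 answer triples and the 12 grid levels.
#'
#' @param q1,q2,q3 Integer vectors of category codes (recycled to a common
#'   length).  `q1` in 1..3, `q2` and `q3` in 1..2.
#' @return Numeric vector of STAGES levels.
#' @examples
#' level_from_answers(1, 1, 1) # 1.0, the scale minimum
#' level_from_answers(3, 2, 2) # 6.5, the scale maximum
#' level_from_answers(2, 2, 1) # 4.0
#' @seealso [answers_from_level()] for the inverse map.
#' @export
level_from_answers <- function(q1, q2, q3) {
  n <- max(length(q1), length(q2), length(q3))
  q1 <- rep_len(as.numeric(q1), n)
  q2 <- rep_len(as.numeric(q2), n)
  q3 <- rep_len(as.numeric(q3), n)
  bad <- function(q, hi) is.na(q) | q %% 1 != 0 | q < 1 | q > hi
  if (any(bad(q1, 3)) || any(bad(q2, 2)) || any(bad(q3, 2))) {
    abort_stagescore(
      "`q1` must be an integer in 1..3, `q2` and `q3` integers in 1..2.",
      "invalid_answer"
    )
  }
  2 * (q1 - 1) + q2 + 0.5 * (q3 - 1)
}

#' Invert a STAGES level back to its answer triple
#'
#' The inverse of [level_from_answers()]: recovers the unique
#' (tier, person, agency) triple that produces each grid level.
#'
#' @param level Numeric vector of STAGES grid values.
#' @return A tibble with integer columns `q1`, `q2`, `q3` and the input
#'   `level`.
#' @examples
#' answers_from_level(c(1.0, 4.0, 6.5))
#' @export
answers_from_level <- function(level) {
  if (!all(is_stages_level(level))) {
    abort_stagescore("All values in `level` must lie on the STAGES grid.",
                     "invalid_level")
  }
  q1 <- as.integer(floor((level - 1) / 2) + 1)
  rem <- level - 2 * (q1 - 1)
  q3 <- as.integer((rem * 2) %% 2 + 1)
  q2 <- as.integer(rem - 0.5 * (q3 - 1))
  tibble(q1 = q1, q2 = q2, q3 = q3, level = level)
}

#' Snap real values to the nearest STAGES level
#'
#' Respondent scores are averages of sentence levels and so fall between grid
#' points; reporting on the STAGES scale requires rounding to the nearest
#' half step.  Exact midpoints (e.g. 3.75) round up, and results are clamped
#' to the scale range \[1.0, 6.5\].
#'
#' @param x Numeric vector of finite values.
#' @return Numeric vector of STAGES grid values.
#' @examples
#' snap_to_grid(c(3.74, 3.75, 0.4, 7.1))
#' @export
snap_to_grid <- function(x) {
  if (any(!is.finite(x))) {
    abort_stagescore("`x` must be finite to snap to the STAGES grid.",
                     "invalid_value")
  }
  pmin(pmax(floor(x * 2 + 0.5) / 2, 1), 6.5)
}
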