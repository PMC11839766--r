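# printed reference cross-tabulation of the 58 validation pairs
# (rows expert MAP, columns protocol STAGES, both on the 12-level grid)
reference_crosstab <- function() {
  m <- rbind(
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(3, 2, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    c(3, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 1, 0, 0, 2, 1, 3, 0, 0, 0, 0, 0),
    c(0, 0, 0, 1, 2, 4, 14, 4, 0, 0, 0, 1),
    c(0, 0, 0, 0, 0, 0, 3, 2, 0, 0, 0, 0),
    c(0, 0, 0, 0, 2, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 1, 0),
    c(0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 2, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  )
  labels <- c("1", "1.5", "2", "2.5", "3", "3.5", "4", "4.5", "5", "5.5",
              "6", "6.5")
  dimnames(m) <- list(rater_a = labels, rater_b = labels)
  storage.mode(m) <- "integer"
  m
}

# a stub backend whose question-1 answers follow a fixed per-run schedule
schedule_backend <- function(q1_codes, q2 = 1L, q3 = 1L) {
  run <- new.env()
  run$i <- 0L
  function(sentence, question_id) {
    if (question_id == 1) {
      run$i <- run$i + 1L
      q1_codes[[(run$i - 1L) %% length(q1_codes) + 1L]]
    } else if (question_id == 2) q2 else q3
  }
}
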