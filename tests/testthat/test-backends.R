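test_that("rendered prompts carry the canonical classification instructions", {
  p1 <- render_prompt(1, "The car is red")
  expect_match(p1, "Classify the following sentence as (1) Concrete, (2) Subtle, or (3) MetAware",
               fixed = TRUE)
  expect_match(p1, "The car is red", fixed = TRUE)
  p2 <- render_prompt(2, "x")
  expect_match(p2, "Classify the following sentence as (1) Individual, (2) Collective",
               fixed = TRUE)
  p3 <- render_prompt(3, "x")
  expect_match(p3, "Classify the following sentence as (1) Passive, (2) Active",
               fixed = TRUE)
  expect_error(render_prompt(1, ""), class = "stagescore_invalid_input")
  expect_error(render_prompt(1, "  "), class = "stagescore_invalid_input")
})

test_that("custom prompt templates must carry exactly one sentence slot", {
  expect_error(stages_prompts(q1 = "no slot here"),
               class = "stagescore_invalid_prompt")
  expect_error(stages_prompts(q1 = "{sentence} and {sentence}"),
               class = "stagescore_invalid_prompt")
  p <- stages_prompts(q3 = "Passive or active? {sentence}")
  expect_equal(render_prompt(3, "He runs", p), "Passive or active? He runs")
})

test_that("parse_category reads codes, names, and rejects garbage", {
  expect_equal(parse_category("(2) Subtle", 1), 2L)
  expect_equal(parse_category("1", 1), 1L)
  expect_equal(parse_category("MetAware", 1), 3L)
  expect_equal(parse_category("the sentence is collective", 2), 2L)
  expect_error(parse_category("maybe", 1), class = "stagescore_unparsable_response")
  expect_error(parse_category("7", 2), class = "stagescore_unparsable_response")
  expect_error(parse_category("(4) something", 1),
               class = "stagescore_unparsable_response")
})

test_that("mock backend classifies every example sentence the prompts cite", {
  q1_examples <- list(
    list("The car is red", 1L), list("I heard a melody", 1L),
    list("She followed the rules", 1L),
    list("I strive to find balance in my life", 2L),
    list("Values guide our decisions", 2L),
    list("The environment is crucial for peace", 2L),
    list("Time is a construct shaping experience", 3L),
    list("Examining awareness reveals hidden biases", 3L),
    list("Reality is shaped by our perceptions", 3L)
  )
  for (ex in q1_examples) {
    expect_equal(mock_classify(ex[[1]], 1), ex[[2]], label = ex[[1]])
  }
  q2_examples <- list(
    list("I went for a walk", 1L), list("The cat is sleeping", 1L),
    list("She wrote an essay", 1L), list("the person listens", 1L),
    list("The team won the game", 2L),
    list("Families gathered for the reunion", 2L),
    list("The town’s economy is growing", 2L),
    list("Ecosystems rely on biodiversity", 2L),
    list("Cultural narratives shape our understanding of history", 2L),
    list("Religions provide moral frameworks", 2L),
    list("Imagining another’s pain can foster empathy", 2L),
    list("Helping others strengthens community bonds", 2L),
    list("Global warming affects ecosystems worldwide", 2L),
    list("Family dynamics influence individual behavior", 2L)
  )
  for (ex in q2_examples) {
    expect_equal(mock_classify(ex[[1]], 2), ex[[2]], label = ex[[1]])
  }
})

test_that("mock backend distinguishes passive from active agency", {
  expect_equal(mock_classify("The team won the game", 3), 2L)
  expect_equal(mock_classify("She wrote an essay", 3), 2L)
  expect_equal(mock_classify("Reality is shaped by our perceptions", 3), 1L)
  expect_equal(mock_classify("The car is red", 3), 1L)
})

test_that("mock backend is a pure function of its inputs", {
  sentences <- generate_sentences(20, seed = 7)$text
  for (q in 1:3) {
    first <- vapply(sentences, mock_classify, integer(1), question_id = q)
    second <- vapply(sentences, mock_classify, integer(1), question_id = q)
    expect_identical(first, second)
  }
})

test_that("remote backend replays from cache without touching the transport", {
  cache <- withr::local_tempfile(fileext = ".jsonl")
  cfg <- backend_config(model = "test-model", cache_path = cache)
  calls <- new.env(); calls$n <- 0L
  transport <- function(prompt, config) {
    calls$n <- calls$n + 1L
    if (grepl("Concrete", prompt)) "(2) Subtle" else "(1)"
  }
  b <- backend_remote(cfg, transport = transport)
  expect_equal(backend_classify(b, "A thought", 1), 2L)
  expect_equal(calls$n, 1L)
  # same request again: served from the in-memory cache
  expect_equal(backend_classify(b, "A thought", 1), 2L)
  expect_equal(calls$n, 1L)
  # a fresh backend reading the same cache file never calls the transport
  b2 <- backend_remote(cfg, transport = function(prompt, config) {
    stop("network must not be touched")
  })
  expect_equal(backend_classify(b2, "A thought", 1), 2L)
  # and the cache record carries the full request context
  rec <- jsonlite::fromJSON(readLines(cache)[1])
  expect_equal(rec$model, "test-model")
  expect_equal(rec$question, 1L)
  expect_equal(rec$code, 2L)
  expect_equal(rec$temperature, 0)
})

test_that("remote backend retries unparsable replies, then drops the run", {
  calls <- new.env(); calls$n <- 0L
  flaky <- function(prompt, config) {
    calls$n <- calls$n + 1L
    if (calls$n == 1) "no idea" else "(2)"
  }
  b <- backend_remote(backend_config(retries = 2), transport = flaky)
  expect_equal(backend_classify(b, "x", 2), 2L)
  expect_equal(calls$n, 2L)

  hopeless <- backend_remote(backend_config(retries = 1),
                             transport = function(p, c) "gibberish")
  expect_error(backend_classify(hopeless, "x", 2),
               class = "stagescore_unparsable_response")
})

test_that("remote backend without transport or cache reports unavailability", {
  b <- backend_remote(backend_config())
  expect_error(backend_classify(b, "x", 1),
               class = "stagescore_backend_unavailable")
})
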