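#' Classifier backends
#'
#' A backend is the object that answers one classification question about one
#' sentence.  Every backend satisfies the same single-method contract —
#' `classify(sentence, question_id)` returns an integer category code — so the
#' scoring pipeline is backend-agnostic.  Two backends ship with the package:
#'
#' * [backend_mock()] — a deterministic keyword-rule classifier derived from
#'   the classification criteria spelled out inside the prompts themselves.
#'   It makes the whole pipeline runnable and testable offline.
#' * [backend_remote()] — a client for a remote large-language-model API with
#'   zero-temperature decoding, retry handling and an append-only JSON-lines
#'   cache.  The transport (the function that actually performs the network
#'   exchange) is injected by the caller; with a fully populated cache a
#'   scoring run performs zero network calls and is bit-reproducible.
#'
#' @name stages_backend
NULL

#' Classify one sentence/question with a backend
#'
#' @param backend A backend object (see [stages_backend]).
#' @param sentence Non-empty character scalar.
#' @param question_id Integer, 1, 2 or 3.
#' @return Integer category code.
#' @export
backend_classify <- function(backend, sentence, question_id) {
  UseMethod("backend_classify")
}

#' @export
backend_classify.stages_backend <- function(backend, sentence, question_id) {
  backend$classify(sentence, question_id)
}

#' @export
backend_classify.function <- function(backend, sentence, question_id) {
  backend(sentence, question_id)
}

new_backend <- function(classify, kind, ...) {
  structure(list(classify = classify, kind = kind, ...),
            class = c(paste0("stages_backend_", kind), "stages_backend"))
}

#' @export
print.stages_backend <- function(x, ...) {
  cat(sprintf("<stages backend: %s>\n", x$kind))
  invisible(x)
}

# ---- mock backend -----------------------------------------------------------

# marker vocabularies transcribed from the prompts' own classification
# criteria; matched case-insensitively on word stems
mock_markers <- list(
  metaware = c("awareness", "aware", "consciousness", "conscious",
               "construct", "reality", "realities", "perception", "perceiv",
               "assumption", "transcend", "paradox", "meta", "witness"),
  subtle = c("value", "balance", "strive", "belief", "believe", "meaning",
             "possibilit", "uncertain", "maybe", "perhaps", "might",
             "ethic", "moral", "crucial", "guid", "abstract", "peace",
             "development", "reflection", "theor", "vision", "fairness",
             "wisdom", "purpose", "insight"),
  collective = c("team", "group", "bus", "train", "famil", "communit",
                 "people", "others", "another", "collectiv", "peers",
                 "world", "they", "them", "their", "humanity",
                 "organization", "organisation", "parties", "we", "our",
                 "us", "societ", "social", "cultur", "ecosystem", "economy",
                 "religion", "empathy", "global", "nation", "crowd"),
  active = c("won", "wins", "win", "wrote", "writes", "went", "go", "goes",
             "builds", "build", "built", "creates", "create", "created",
             "makes", "make", "made", "paints", "paint", "organizes",
             "organize", "leads", "lead", "helps", "help", "helping",
             "strengthens", "strengthen", "shapes", "shape", "shaping",
             "affects", "affect", "influences", "influence", "provides",
             "provide", "fosters", "foster", "guides", "guide", "examines",
             "examine", "examining", "reveals", "reveal", "challenges",
             "challenge", "acts", "act", "initiates", "initiate", "drives",
             "drive", "works", "work", "gathered", "gather", "followed",
             "follow", "strive", "strives", "rely", "relies", "uses", "use",
             "climbs", "climb", "explores", "explore", "teaches", "teach")
)

has_marker <- function(sentence, markers) {
  words <- c("bus", "train", "they", "them", "their", "we", "our", "us",
             "won", "win", "go", "act", "use", "meta")
  any(vapply(markers, function(m) {
    pattern <- if (m %in% words) paste0("\\b", m, "\\b") else m
    grepl(pattern, sentence, ignore.case = TRUE)
  }, logical(1)))
}

#' Deterministic keyword-rule classification
#'
#' A pure function implementing the mock backend's rules.  The tier question
#' uses marker precedence MetAware > Subtle > Concrete (mirroring the
#' prompts' instruction to identify the primary focus); the person question
#' uses the prompt's collective word list with Individual as the default; the
#' agency question marks a sentence Active when an agentive main verb is
#' present and no passive-voice construction precedes it, defaulting to
#' Passive.
#'
#' @inheritParams render_prompt
#' @return Integer category code.
#' @examples
#' mock_classify("The car is red", 1)            # 1, Concrete
#' mock_classify("Values guide our decisions", 1) # 2, Subtle
#' mock_classify("The team won the game", 2)      # 2, Collective
#' @export
mock_classify <- function(sentence, question_id) {
  check_question_id(question_id)
  if (!is.character(sentence) || length(sentence) != 1 || is.na(sentence) ||
      !nzchar(trimws(sentence))) {
    abort_stagescore("`sentence` must be a non-empty string.", "invalid_input")
  }
  if (question_id == 1) {
    if (has_marker(sentence, mock_markers$metaware)) return(3L)
    if (has_marker(sentence, mock_markers$subtle)) return(2L)
    return(1L)
  }
  if (question_id == 2) {
    if (has_marker(sentence, mock_markers$collective)) return(2L)
    return(1L)
  }
  # q3: passive-voice construction wins, then agentive verbs, else passive
  passive_voice <- grepl(
    "\\b(am|is|are|was|were|be|been|being)\\s+\\w+(ed|en|wn)\\b",
    sentence, ignore.case = TRUE
  )
  if (passive_voice) return(1L)
  if (has_marker(sentence, mock_markers$active)) return(2L)
  1L
}

#' Offline keyword-rule backend
#'
#' Wraps [mock_classify()] in the backend contract.  Deterministic: identical
#' input yields identical output across processes, so the median-of-runs
#' protocol collapses to a single run.
#'
#' @return A backend object.
#' @examples
#' b <- backend_mock()
#' backend_classify(b, "The team won the game", 2)
#' @export
backend_mock <- function() {
  new_backend(mock_classify, kind = "mock")
}

# ---- remote backend ---------------------------------------------------------

#' Remote LLM backend configuration
#'
#' @param model Model identifier string.
#' @param temperature Sampling temperature; the protocol default is 0 so the
#'   decoder is as deterministic as the provider allows.
#' @param top_p Nucleus-sampling mass in (0, 1]; kept small by default to
#'   further reduce stochasticity.
#' @param max_tokens Maximum reply length in tokens; replies are a code plus a
#'   category name, so a small cap suffices.
#' @param retries How many times an unparsable reply is re-requested before
#'   that run is dropped.
#' @param cache_path Optional path to a JSON-lines cache file.  Every
#'   request/reply is appended, keyed by (model, question, sentence,
#'   temperature, top_p); cache hits short-circuit the network.
#' @return A list of class `stages_backend_config`.
#' @export
backend_config <- function(model = "gpt-4o", temperature = 0, top_p = 0.1,
                           max_tokens = 16, retries = 2, cache_path = NULL) {
  stopifnot(is.numeric(temperature), temperature >= 0,
            is.numeric(top_p), top_p > 0, top_p <= 1,
            max_tokens >= 1, retries >= 0)
  structure(list(model = model, temperature = temperature, top_p = top_p,
                 max_tokens = max_tokens, retries = retries,
                 cache_path = cache_path),
            class = "stages_backend_config")
}

cache_key <- function(config, question_id, sentence) {
  paste(config$model, question_id, sentence, format(config$temperature),
        format(config$top_p), sep = "\x1f")
}

read_cache <- function(path) {
  if (is.null(path) || !file.exists(path)) return(list())
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  records <- lapply(lines, jsonlite::fromJSON)
  out <- list()
  for (rec in records) {
    key <- paste(rec$model, rec$question, rec$sentence,
                 format(rec$temperature), format(rec$top_p), sep = "\x1f")
    out[[key]] <- rec
  }
  out
}

append_cache <- function(path, record) {
  if (is.null(path)) return(invisible(NULL))
  line <- jsonlite::toJSON(record, auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(NULL)
}

#' Remote LLM backend with response cache
#'
#' Classifies sentences through a remote model.  The network exchange is
#' delegated to `transport`, a function `(prompt, config) -> reply text`;
#' supplying the transport keeps the package free of provider-specific HTTP
#' code and makes the backend testable offline.  Replies are parsed with
#' [parse_category()]; unparsable replies are retried up to `config$retries`
#' times and then raise an error that the pipeline turns into a dropped run.
#' All traffic is appended to the JSON-lines cache so a re-run with the same
#' cache performs no network calls at all.
#'
#' @param config A [backend_config()].
#' @param prompts A [stages_prompts()] object.
#' @param transport Function of `(prompt, config)` returning the raw reply
#'   text, or `NULL` (the default) to run purely from the cache: a cache miss
#'   then raises a backend-unavailable error.
#' @return A backend object.
#' @export
backend_remote <- function(config = backend_config(),
                           prompts = stages_prompts(),
                           transport = NULL) {
  cache <- read_cache(config$cache_path)
  classify <- function(sentence, question_id) {
    check_question_id(question_id)
    key <- cache_key(config, question_id, sentence)
    hit <- cache[[key]]
    if (!is.null(hit)) {
      return(as.integer(hit$code))
    }
    if (is.null(transport)) {
      abort_stagescore(
        "No transport configured and no cached reply for this request.",
        "backend_unavailable"
      )
    }
    prompt <- render_prompt(question_id, sentence, prompts)
    attempts <- config$retries + 1
    last_err <- NULL
    for (i in seq_len(attempts)) {
      reply <- tryCatch(transport(prompt, config), error = function(e) {
        abort_stagescore(
          paste0("Transport failure: ", conditionMessage(e)),
          "backend_unavailable", parent = e
        )
      })
      code <- tryCatch(parse_category(reply, question_id),
                       error = function(e) e)
      if (!inherits(code, "error")) {
        record <- list(model = config$model, question = question_id,
                       sentence = sentence,
                       temperature = config$temperature,
                       top_p = config$top_p, reply = reply, code = code,
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
        append_cache(config$cache_path, record)
        cache[[key]] <<- record
        return(as.integer(code))
      }
      last_err <- code
    }
    abort_stagescore(
      sprintf("Reply for question %d unparsable after %d attempt(s).",
              question_id, attempts),
      "unparsable_response", parent = last_err
    )
  }
  new_backend(classify, kind = "remote", config = config, prompts = prompts)
}
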