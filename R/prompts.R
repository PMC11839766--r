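#' Default classification prompts
#'
#' The three prompt templates used to classify a sentence on the tier,
#' person-perspective and agency dimensions.  Each template contains exactly
#' one `{sentence}` insertion slot.  The wording was tuned against expert
#' scoring and is deliberately frozen: re-wording the prompts changes the
#' classifier distribution, so any change should be treated as a new protocol
#' version and re-validated.
#'
#' @param q1,q2,q3 Optional replacement templates; each must contain exactly
#'   one `{sentence}` slot.
#' @return An object of class `stages_prompts`: a list with elements `q1`,
#'   `q2`, `q3`.
#' @examples
#' p <- stages_prompts()
#' cat(substr(p$q1, 1, 80), "...\n")
#' @export
stages_prompts <- function(q1 = NULL, q2 = NULL, q3 = NULL) {
  defaults <- list(q1 = prompt_q1_default, q2 = prompt_q2_default,
                   q3 = prompt_q3_default)
  out <- list(q1 = q1 %||% defaults$q1, q2 = q2 %||% defaults$q2,
              q3 = q3 %||% defaults$q3)
  for (id in names(out)) {
    n_slots <- lengths(regmatches(out[[id]],
                                  gregexpr("\\{sentence\\}", out[[id]])))
    if (!identical(n_slots, 1L)) {
      abort_stagescore(
        sprintf("Prompt template `%s` must contain exactly one {sentence} slot.", id),
        "invalid_prompt"
      )
    }
  }
  structure(out, class = "stages_prompts")
}

prompt_q1_default <- paste0(
  "Classify the following sentence as (1) Concrete, (2) Subtle, or (3) ",
  "MetAware according to Terri O’Fallon’s classification protocol.\n\n",
  "A Concrete sentence refers to tangible objects or phenomena directly ",
  "perceivable through the senses or personal experiences tied to specific, ",
  "observable events. It often involves physical objects, direct sensory ",
  "descriptions, or basic actions. Examples include “The car is red,” ",
  "“I heard a melody,” and “She followed the rules.”\n\n",
  "A Subtle sentence refers to abstract concepts, ideas, or phenomena not ",
  "directly tied to sensory experience. It often involves reflection, moral ",
  "or ethical considerations, theoretical reasoning, future possibilities, ",
  "or language of uncertainty. Examples include “I strive to find balance ",
  "in my life,” “Values guide our decisions,” and “The ",
  "environment is crucial for peace.”\n\n",
  "A MetAware sentence refers to high-level abstraction, awareness, or ",
  "consciousness of Concrete and Subtle phenomena, often questioning ",
  "assumptions about reality. It focuses on complexity, philosophical ",
  "considerations, and transcendent understanding. Examples include ",
  "“Time is a construct shaping experience,” “Examining ",
  "awareness reveals hidden biases,” and “Reality is shaped by our ",
  "perceptions.” Identify the primary focus of the sentence and classify ",
  "it accordingly.\n\nSentence: {sentence}"
)

prompt_q2_default <- paste0(
  "Classify the following sentence as (1) Individual, (2) Collective ",
  "according to Terri O’Fallon’s classification protocol.\n\n",
  "Individual Sentence (1): These sentences focus on single entity, personal ",
  "experience, or individual actions.\n\n",
  "Characteristics: Refers to a single person or object, often express with ",
  "I or my, He or She of his or her and do not consider collective objects ",
  "(family, group, community, collectivity, humanity, …). Describes ",
  "personal experiences, qualities or actions of one individual. Example: ",
  "I went for a walk, The cat is sleeping, She wrote an essay, the person ",
  "listens.\n\n",
  "Collective Sentence (2): A Collective sentence refers to objects that ",
  "involve relationships, groups, processes, or systems encompassing ",
  "multiple individual entities.\n\n",
  "Characteristics: Presence of collective words: team, group, bus, train, ",
  "family, community, people, others, collective, peers, world, they, ",
  "humanity, organization, parties…. Example: The team won the game, ",
  "Families gathered for the reunion. Processes and Systems: Discusses ",
  "processes or systems that involve multiple individuals or entities. ",
  "Example: The town’s economy is growing,” “Ecosystems rely on ",
  "biodiversity. Cultural and Social Narratives: Describes value systems, ",
  "cultural contexts, or societal narratives. Example: Cultural narratives ",
  "shape our understanding of history, Religions provide moral frameworks. ",
  "Relational and Perspective-taking: Involves early forms of relational ",
  "understanding and empathy. Example: Imagining another’s pain can ",
  "foster empathy, Helping others strengthens community bonds. Complex ",
  "Systems and Interrelationships: Refers to complex systems, ",
  "interrelationships of abstract concepts, or holistic world-systems. ",
  "Example: Global warming affects ecosystems worldwide, Family dynamics ",
  "influence individual behavior. For sentences that mix individual and ",
  "collective subjects, identify where the main attention goes and classify ",
  "the sentence accordingly.\n\nSentence: {sentence}"
)

prompt_q3_default <- paste0(
  "Classify the following sentence as (1) Passive, (2) Active according to ",
  "Terri O’Fallon’s framework for distinguishing agency: ",
  "(1) Passive: The subject is receiving action, being influenced, or ",
  "emphasizing receptivity and external causation. Language reflects a focus ",
  "on being acted upon or experiencing without direct agency. ",
  "(2) Active: The subject is the agent initiating action, exerting ",
  "influence, or emphasizing doing and causation. Language reflects direct ",
  "agency and intentional action.\n\nSentence: {sentence}"
)

#' Render a classification prompt for a sentence
#'
#' @param question_id Integer, 1, 2 or 3.
#' @param sentence Non-empty character scalar.
#' @param prompts A [stages_prompts()] object.
#' @return The question's template with the sentence substituted into the
#'   `{sentence}` slot.
#' @examples
#' cat(render_prompt(3, "I went for a walk"))
#' @export
render_prompt <- function(question_id, sentence, prompts = stages_prompts()) {
  check_question_id(question_id)
  if (!is.character(sentence) || length(sentence) != 1 || is.na(sentence) ||
      !nzchar(trimws(sentence))) {
    abort_stagescore("`sentence` must be a non-empty string.", "invalid_input")
  }
  template <- prompts[[paste0("q", question_id)]]
  sub("{sentence}", sentence, template, fixed = TRUE)
}

# categories per question, in code order
question_categories <- list(
  `1` = c("Concrete", "Subtle", "MetAware"),
  `2` = c("Individual", "Collective"),
  `3` = c("Passive", "Active")
)

check_question_id <- function(question_id) {
  if (!length(question_id) == 1 || !question_id %in% 1:3) {
    abort_stagescore("`question_id` must be 1, 2 or 3.", "invalid_input")
  }
  invisible(as.integer(question_id))
}

#' Parse a classifier reply into a category code
#'
#' Extracts the answer from a free-text backend reply.  The first digit in
#' the reply (parenthesised or bare) is used if it lies in the question's
#' valid range; otherwise the reply is matched case-insensitively against the
#' category names (Concrete/Subtle/MetAware, Individual/Collective,
#' Passive/Active).
#'
#' @param raw Character scalar, the backend reply.
#' @param question_id Integer, 1, 2 or 3.
#' @return Integer category code.
#' @examples
#' parse_category("(2) Subtle", 1)
#' parse_category("MetAware", 1)
#' @export
parse_category <- function(raw, question_id) {
  check_question_id(question_id)
  cats <- question_categories[[as.character(question_id)]]
  if (is.character(raw) && length(raw) == 1 && !is.na(raw)) {
    digit <- regmatches(raw, regexpr("[0-9]+", raw))
    if (length(digit) == 1) {
      code <- suppressWarnings(as.integer(digit))
      if (!is.na(code) && code >= 1 && code <= length(cats)) {
        return(code)
      }
      abort_stagescore(
        sprintf("Reply %s contains code %s, outside 1..%d for question %d.",
                encodeString(raw, quote = '"'), digit, length(cats), question_id),
        "unparsable_response"
      )
    }
    hit <- which(vapply(cats, function(nm) {
      grepl(nm, raw, ignore.case = TRUE)
    }, logical(1)))
    if (length(hit) >= 1) {
      return(as.integer(hit[[1]]))
    }
  }
  abort_stagescore(
    sprintf("Could not parse a question-%d category from reply %s.",
            question_id, encodeString(as.character(raw)[1], quote = '"')),
    "unparsable_response"
  )
}
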