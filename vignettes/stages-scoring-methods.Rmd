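---
title: "Scoring sentence completion tests on the STAGES scale: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sentence completion tests on the STAGES scale: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagescore)
library(dplyr)
```

## The scoring model

Sentence completion tests (SCTs) measure ego development: a respondent
completes unfinished sentence stems, and trained experts place each
completion on an ordinal developmental scale.  The STAGES framework scores a
completion by answering three questions about it:

1. **Tier of object awareness** — does the sentence foreground Concrete
   objects (tangible, sensory), Subtle objects (abstract ideas, values,
   possibilities), or MetAware objects (awareness of awareness, constructs of
   reality)?
2. **Person perspective** — does it foreground an Individual entity or a
   Collective/system?
3. **Agency** — is the subject Passive (receiving action) or Active
   (initiating it)?

The three categorical answers determine one of twelve levels on the
half-step grid 1.0–6.5 via a decision tree that this package encodes in
closed form:

$$\mathrm{level} = 2\,(q_1 - 1) + q_2 + \tfrac{1}{2}\,(q_3 - 1)$$

with $q_1 \in \{1,2,3\}$, $q_2, q_3 \in \{1,2\}$.  Each tier owns a block of
four consecutive half-steps (Concrete 1.0–2.5, Subtle 3.0–4.5, MetAware
5.0–6.5); the Collective focus adds a whole step inside the block and the
Active orientation a half step.  This is the unique order-consistent
assignment of (tier, person, agency) blocks to the grid, and the package
verifies exhaustively that it is a bijection between the 12 triples and the
12 levels.

```{r bijection}
triples <- expand.grid(q1 = 1:3, q2 = 1:2, q3 = 1:2)
sort(level_from_answers(triples$q1, triples$q2, triples$q3))
```

The framework also describes a four-way refinement of the agency question
(receptive, active, reciprocal, interpenetrative).  The scoring prompt the
protocol actually uses is binary Passive/Active, so the binary form is what
the package implements.

## Classifier backends

The three questions are answered per sentence by a *backend*, any object
satisfying the single-method contract `(sentence, question_id) -> code`.
Two backends ship with the package:

* **`backend_remote()`** sends the package's prompt templates to a
  large-language-model API.  The decoding defaults follow the protocol's
  determinism goal: temperature 0 and a small nucleus-sampling mass
  (`top_p = 0.1`).  Neither the provider's top-p nor its token cap is
  dictated by the protocol, so both are configuration with documented
  defaults.  Because remote APIs cannot guarantee determinism even at
  temperature 0, every request/reply is appended to a JSON-lines cache keyed
  by (model, question, sentence, temperature, top-p); with a populated cache
  a scoring run makes zero network calls and is bit-reproducible.  The cache,
  not the decoder settings, is the package's reproducibility boundary.  The
  HTTP exchange itself is injected by the caller as a `transport` function,
  keeping the package free of provider-specific code.
* **`backend_mock()`** is a deterministic keyword-rule classifier whose
  rules are transcribed from the classification criteria spelled out inside
  the prompts themselves (e.g. the collective word list "team, group, bus,
  train, family, community, people, others…").  Tier uses marker precedence
  MetAware > Subtle > Concrete, mirroring the prompt's "identify the primary
  focus" instruction; person focus defaults to Individual unless a
  collective marker appears; agency marks passive-voice constructions
  Passive, then agentive verbs Active, defaulting to Passive.  The mock is a
  testing device that makes the full pipeline runnable offline — it is not a
  model of expert judgement.

Free-text replies are parsed by `parse_category()`: the first digit in the
reply wins if it is in range, otherwise a case-insensitive category-name
match.  The parsing rule is a documented reconstruction (no canonical rule
exists); an unparsable reply is retried up to a configured count and the run
is then dropped with a warning, a sentence needing at least one successful
run per question.

## Median-of-runs stabilisation

A stochastic backend can answer the same question differently across runs,
and a flip in any one answer moves the final level.  The protocol therefore
repeats the three-question classification `n_runs` times (default 10) and
scores the sentence with the *median* of the per-run levels.  Two details
are deliberate:

* **Lower median.**  For even run counts the interpolated median can fall
  off the grid (e.g. 3.25).  The package uses the lower median — the element
  at position $\lceil n/2 \rceil$ of the sorted runs — which is always an
  attained grid value.
* **Both median series.**  Per-question medians are recorded alongside the
  median of per-run levels; the run-count calibration regresses both.

`run_count_regression()` formalises "how many runs are enough": regress the
median outcome on the run count over windows $[s, 30]$ for
$s \in \{3, 5, 10, 15, 20\}$ and look for persistently flat slopes.
`stabilization_point()` returns the smallest window start from which *all*
later windows are flat at the supplied tolerance, flagging the series
unstable when no such start exists — a flat early window followed by a
sloped later one is not accepted, since the drift has evidently not died
out.  This rule is a documented formalisation; with a deterministic backend
every slope is exactly zero and a single run suffices.

## Respondent aggregation and the minimum item count

Group-level use cares about a respondent's *average* level, not single
sentences.  `score_respondent()` averages the sentence medians and snaps the
mean back to the grid (`snap_to_grid()`: nearest half step, exact midpoints
rounding up — the protocol does not fix a tie rule, so the package fixes
half-up and documents it; out-of-range raw reals are clamped, which can only
matter for caller-supplied values since means of grid levels stay in range).

How many sentences does the average need?  `subsample_stability()` draws
`n_combos` random subsets of each candidate size from a scored item set and
reports the mean and standard deviation of
$|\text{subset mean} - \text{full-set mean}|$.  Both fall toward zero as the
subset approaches the full set; the protocol's recommendation derived from
this analysis is ten sentences, with five as an accepted floor, and those
two values are the package defaults (`min_sentences = 5`, recommended 10).
Two sampling conventions are fixed and documented rather than prescribed by
the protocol: combinations are drawn without replacement *within* a
combination but may repeat *across* combinations (unique draws are
impossible whenever $\binom{N}{k}$ is small), and the standard deviation is
the population form (divide by $n$).

```{r subsample}
fx <- load_fixture("table3")
subsample_stability(fx$stages_score, sizes = c(5, 10, 20), n_combos = 2000,
                    seed = 1)
```

## Agreement statistics

Validation compares two raters — expert scores and protocol scores — on the
same sentences.  `build_crosstab()` forms the $12 \times 12$ contingency
table, always indexed by the full grid (empty categories included) so
printed layouts are comparable; the padding provably does not change kappa.

`weighted_kappa()` computes Cohen's weighted kappa with quadratic
disagreement weights $w_{ij} = (i - j)^2 / (k - 1)^2$,

$$\kappa_w = 1 - \frac{\sum_{ij} w_{ij}\,p_{ij}}{\sum_{ij} w_{ij}\,r_i c_j},$$

which penalises disagreements by squared category distance — appropriate for
an ordinal scale where a two-step miss is worse than a half-step miss.  The
standard error is the large-sample non-null variance of Fleiss, Cohen and
Everitt (1969), and the 95% confidence interval is $\kappa \pm 1.96\,se$.
Several asymptotic variance variants circulate; the package's tests pin this
implementation against an independent reference implementation and against
the published validation analysis of the bundled dataset to five and four
decimals respectively.

```{r kappa}
fit <- weighted_kappa(fx, score_a = "map_score", score_b = "stages_score")
fit
tidy(fit)
```

`aggregate_agreement()` asks the scale-use question: if scores are consumed
as *averages over item subsets*, how well do the raters agree on those
averages?  It draws `n_combos` combinations of `combo_size` items, averages
each rater over the combination, snaps both means to the grid, and computes
the weighted kappa over the resampled snapped mean-pairs.  Two caveats are
inherent to the procedure and stated rather than hidden:

* The resampled mean-pairs share underlying items, so they are not
  independent; the attached asymptotic standard error is descriptive, not
  inferential.
* Aggregation shrinks both raters' spread (standard error of a mean of $k$
  items) while any systematic offset between raters survives averaging.
  Chance-corrected agreement on the aggregated scale therefore reflects the
  mean offset between raters much more strongly than the per-item kappa
  does, and can be substantially *lower* than the per-item kappa even when
  the correlation of the aggregated scores is high — with heterogeneous
  marginals, $\kappa_w$ is bounded away from the Pearson correlation of the
  same pairs.  Users comparing aggregate kappas across tools should check
  which statistic the other tool actually computes, because
  correlation-style statistics on the same resampled means give visibly
  larger values.

## Synthetic data with known ground truth

Two generators make every estimator testable without external data:

* `generate_paired_scores()` draws pairs from a **copy-mixture** model:
  rater A from a marginal over the grid, rater B a copy of A with
  probability $a$ and otherwise an independent draw from the same marginal.
  The observed expected weighted disagreement is then $(1-a)$ times the
  chance-expected disagreement, so the population quadratic-weighted kappa
  equals $a$ for *any* marginal — an analytic oracle for parameter-recovery
  tests ($|\hat\kappa - a| < 0.03$ at $n = 5000$ is asserted in the test
  suite for $a \in \{0, 0.5, 0.8, 1\}$).
* `generate_sentences()` assembles subject/verb/object sentences from a
  vocabulary locked to the mock backend's marker rules: the subject encodes
  the person answer, the verb form the agency answer, the object the tier.
  The mock pipeline therefore recovers the intended triple — and level — for
  100% of generated sentences, which is asserted exactly.  These sentences
  validate the machinery end to end; they are deliberately **not** a
  simulation of human SCT responses, so a perfect round-trip says nothing
  about accuracy on real text, where validation against expert scores (the
  bundled dataset) is the relevant evidence.

## Numerical and design choices

* **Grid arithmetic.**  Levels are doubled to integers for rounding;
  `snap_to_grid()` is idempotent and order-preserving, midpoints round up.
  Means of half-step values are exactly representable in binary floating
  point, so snapping is not subject to representation error.
* **Seeds.**  Every stochastic operation takes an explicit `seed` and
  restores the caller's RNG state on exit.  With a fixed seed and a
  mock/cached backend the entire pipeline is bit-reproducible.
* **Typed errors.**  All failures raise classed conditions
  (`stagescore_invalid_level`, `stagescore_unparsable_response`,
  `stagescore_insufficient_items`, …) so pipelines can dispatch on failure
  kind.
* **Degenerate inputs.**  Kappa requires at least two observed categories
  and positive expected disagreement; tables failing either raise
  `stagescore_degenerate_table` rather than returning NaN.
* **Problem sizes.**  The validation analyses in the test suite and the
  acceptance script use the 58-sentence bundled dataset, 5,000 resampled
  combinations, and synthetic samples of 400–8,000 pairs — sizes at which
  Monte-Carlo error is comfortably below the asserted tolerances while the
  whole suite runs in seconds.

## Limitations

* The package validates a *protocol*; it does not certify any particular
  LLM.  Model choice, prompt drift and provider nondeterminism are outside
  the package's control — the cache makes a given run reproducible, not a
  given model reliable.
* The keyword mock is a lower bound on linguistic subtlety by design;
  passing the round-trip suite demonstrates pipeline correctness, not
  scoring validity on human text.
* Aggregate agreement treats resampled means as observations (see above);
  its standard error should not be used for hypothesis tests.
* Individual diagnostic use is explicitly out of scope: the intended unit of
  analysis is the group or organisation, where averaging over many
  completions stabilises the estimate.
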