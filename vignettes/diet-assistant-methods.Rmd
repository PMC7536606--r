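---
title: "Methods: a knowledge-based diet assistant for dementia caregivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a knowledge-based diet assistant for dementia caregivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietassist)
```

## The problem and the system

Caregivers of people with Alzheimer disease and related dementias (ADRD)
face a practical question several times a day: *is this food right for
this patient, now?* The answer depends on interacting constraints —
neuroprotective dietary patterns, disease-specific rules (diabetes is
the common comorbidity modeled here), allergies, dislikes, religious
constraints, and the caregiver's own time, budget, and background.
`dietassist` implements the back end of a conversational assistant that
answers such questions from an explicit knowledge base rather than from
an opaque model, so every answer can cite the rule it came from.

The package has six cooperating layers: ontology knowledge base,
rule-based inference engine, guideline constraint library, finite-state
dialogue manager, personalized services, and an evaluation harness,
plus a deterministic fixture generator that supplies every input.

## Knowledge representation

The knowledge base covers three conceptual areas — user profiles
(patient and caregiver), ADRD diet support, and food/nutrition — as a
single typed concept graph. Classes are connected by IS-A edges whose
transitive closure defines subsumption; individuals attach to classes
by the *type* relation and carry property assertions. `partition_kb()`
separates the terminological half (TBox: classes, IS-A, disjointness,
synonyms) from the assertional half (ABox: individuals, foods,
recipes); `merge_kb()` restores the original exactly, and a test
asserts this round-trip on the full fixture KB.

Design choices worth noting:

* **IS-A cycles are a hard load error** (the error names the cycle).
  Backward chaining and MIND classification both need a well-founded
  class order, and a cyclic ontology is almost certainly an authoring
  mistake rather than a meaningful model.
* **Surface matching is case-insensitive; concept ids are
  case-sensitive.** Utterances arrive as free text, so the vocabulary
  maps normalized terms; the graph itself keeps exact ids.
* **Synonym collisions are rejected at load** so that every surface
  term resolves to exactly one concept. Where a class label would
  collide with a food name, the fixture generator gives the food a more
  specific display name (e.g. *extra virgin olive oil* under the
  `OliveOil` class).
* **Nutrients are stored per 100 g** (FoodData Central convention);
  recipe totals are derived per serving from ingredient gram amounts.
* Two serializations are accepted: a canonical JSON dialect and a
  Turtle subset (`rdfs:subClassOf`, `rdf:type`/`a`, `rdfs:label`,
  `owl:disjointWith`). The subset parser is intentionally minimal; the
  JSON dialect is the documented interchange format.

## Inference

Rules are *safe, function-free Horn clauses* — a Datalog subset of the
SWRL idea — with numeric comparisons (`lt`, `le`, `eq`, `ge`, `gt`,
`ne`), arithmetic on bound values (`add`, `sub`, `mul`, `div` binding
their third argument), and stratified negation-as-failure for
exclusion-style rules. This restriction is deliberate: it is decidable,
terminating, and testable against a reference semantics, which full
description-logic reasoning is not at this scale.

`prove()` is goal-driven: from the goal predicate it collects only the
predicates reachable through rule bodies, stratifies them with respect
to negation (negation through recursion is rejected), and saturates
each stratum with a fixpoint over memoized answer tables. Repeated
subgoals hit the table instead of recursing, so cyclic rule graphs
terminate; each derived fact records the rule and ground body that
first produced it, from which `prove()` reconstructs a goal-to-leaf
trace (one row per rule application — a directly asserted fact has an
empty trace). On safe positive programs this computes exactly the
forward-chaining least fixpoint; the test suite asserts identity of the
two on hundreds of randomly generated programs, with the
forward-chaining oracle implemented independently in the test helpers
by brute-force substitution enumeration.

IS-A subsumption is compiled into rules (`Sub(?x) -> Super(?x)`), so
entailed class memberships carry traces like any other conclusion, and
`check_satisfiability()` — which reports individuals entailed to belong
to two disjoint classes — can show *why* each conflict holds. This is
deliberately a limited consistency check, not a tableau procedure.

Enumeration order everywhere (query answers, candidate ranking ties) is
lexicographic on constants, purely for reproducibility.

## Guideline knowledge

The rule base encodes three citable sources:

| Constraint | Value | Unit / basis |
|---|---|---|
| MIND encourage | vegetables, berries, nuts, olive oil, whole grains, fish, beans, poultry | food category |
| MIND limit | butter, margarine, cheese, red meat, fried food, pastries, sweets | food category |
| HHS per-meal energy | 800–850 | kcal; man, three meals/day |
| ADA dinner energy | 25% of EER | kcal/day basis |
| ADA protein share | 20–30% | % of meal energy |
| ADA sugar share | < 10% | % of meal energy |

Choices the sources leave open, fixed here:

* **Energy conversion** uses Atwater factors (4/4/9 kcal per g of
  protein/carbohydrate/fat; sugar at 4), with percent shares always
  computed against the *tabulated* meal energy.
* **Calorie-target tolerance**: a degenerate target *t* (the ADA dinner
  case) matches within ±5% of *t*; a printed range (HHS 800–850)
  matches when inside the range. The sources state no tolerance; ±5%
  keeps the 25%-of-EER rule meaningful without making it unachievable.
* **EER**: taken from the profile when present; otherwise the Institute
  of Medicine adult equations at a low-active physical-activity level
  with sex-specific reference anthropometrics (77 kg/1.76 m men,
  64 kg/1.62 m women). The diabetic-dinner rule, however, *requires* a
  profile EER and raises a missing-data error otherwise — by design, so
  the dialogue layer elicits it rather than silently guessing.
* **Precedence**: the disease-specific ADA dinner rule wins over the
  HHS demographic rule when both could apply (the HHS rule is applied
  only to its exact stated case: male, three meals, non-diabetic; other
  demographics get EER/meals ± 10%, flagged as an extension). Hard
  exclusions (allergy, religious constraint) are non-negotiable; a MIND
  "limit" classification is advisory in recommendation (reported, not a
  veto) but decisive in a direct suitability query, where a limited food
  is `not_recommended`.

Every violation and every verdict reason carries a provenance string,
and those exact strings appear in the shipped rule file
(`inst/extdata/guideline_rules.txt`), so explanations are always
traceable to a citable rule; a test enforces this.

## Dialogue management

The conversation layer replaces a commercial voice stack with
transparent, testable parts. Intent detection normalizes the utterance,
replaces surface terms by canonical concept ids using the KB vocabulary
(longest n-gram first), extracts typed slot values (food concepts, meal
types, counts, durations, recall windows), and scores the expanded
token set against each intent's sample utterances by Jaccard overlap
with slot placeholders instantiated. The 0.5 threshold is configurable;
below it the assistant asks for clarification. A transparent scorer was
chosen over any statistical model on purpose: determinism is an
invariant (identical inputs give identical results) and failures are
inspectable.

Each of the five service categories — proper-diet tips, eating-challenge
handling, food/nutrition explanation, meal suggestion, diet-history
recall — has its own state graph starting at `S0`; transition conditions
are evaluated in declaration order, first match wins, and unmatched
input self-loops with a re-prompt (at most 3 re-prompts before the
intent is abandoned with an apology). Slot filling accepts
over-answering (several slots in one reply) and never overwrites a
confirmed slot; long-term context (allergies, stage, preferences) is
installed at session start and persists, while short-term context
(latest food discussed, chosen meal) expires after 5 turns — "a few
turns" made concrete. A sentiment hook exists in the interpretation
pipeline but always reports neutral; defining real sentiment extraction
is out of scope.

Responses are template-rendered per caregiver education tier: the basic
tier uses short sentences with no technical nutrient terms or
percentages; the advanced tier includes the numeric rationale (kcal and
percent-of-energy figures). The tier contract is tested literally (no
`%` token in basic output).

## Services

Recommendation filters candidates by meal type, session rejections, and
the full constraint check, then ranks by (1) count of MIND-encouraged
ingredients, descending, (2) distance of per-serving energy from the
calorie-target midpoint, (3) id. The ordering itself is a design
choice — the sources say only that multiple factors are considered — so
it is documented and deterministic rather than claimed as prescribed.
Rejection memory is session-scoped: a rejected recipe is never
re-offered in the same session and the memory clears with the session.
Diet history is an append-only record with daily and weekly recall
(7 days ending at the anchor date); persistence is a JSONL file per
patient rather than a database.

## Synthetic data: what it emulates and what it does not

The generator produces the study conditions, not a dial to tune:

* **Foods** (default 50) span every MIND category with at least one
  item per encouraged and limited category. Per-category nutrient
  ranges are invented but plausible per 100 g; energy is *derived* from
  the drawn macros by Atwater factors with ±5% jitter, so the
  tabulated-vs-derived energy sanity band (30%) holds by construction.
  At least 20% of items carry synonyms, exercising the vocabulary.
* **The persona** is the reference household: a female caregiver and
  her 65-year-old father, early-stage ADRD with type 2 diabetes, EER
  2000 kcal/day (so the ADA dinner target is 500 kcal), shellfish
  allergy (class-level, exercising IS-A exclusion), a 40-minute cooking
  limit, and a 12-per-meal budget.
* **Recipes** (20) are designed: exactly two dinner recipes are tuned
  (by a deterministic iterative scaler) into the full diabetic-dinner
  band, and one dinner recipe violates each constraint class (sugar,
  protein, calorie, time, budget, allergy). The manifest records the
  generator's own arithmetic for each recipe, which the test suite
  compares against the package's checker — two independent routes to
  the same admissibility set.
* **Scripts** (34 across the three evaluated categories) cover happy
  paths, slot elicitation, over-answering, rejection-then-alternative,
  synonym use, and one adversarial never-terminating script per
  category that must fail at exactly the 20-turn threshold.

What passing on these fixtures does **not** show: robustness to real
spoken-language variety (the scripts are written near the intent
templates, as scripted lab testing is), real food-composition data, or
clinical validity of recommendations for actual patients. The fixtures
make the *logic* fully checkable; they do not make the system clinically
evaluated.

## Evaluation

A dialogue succeeds when a script-declared satisfying action occurs
within the 20-turn threshold; exceeding it without one marks the
dialogue failed (`success_rate` = 100·n/N). Correctness of each
substantive response is judged by an automated checker that re-derives
the answer — for a recommended recipe, that its violation list is empty
for this patient and caregiver; for a snack, that no exclusion applies
and it is not MIND-limited; for a verdict, that an independent
recomputation agrees. This replaces a human judgment with an
operational criterion, which is a documented divergence: the automated
judge can only check guideline/profile consistency, not helpfulness.
Timing metrics are hardware-dependent and are not reported.

Problem sizes used throughout (50 foods, 20 recipes, 34 scripts, 500
random programs for the oracle comparison) are the package's chosen
study scale: large enough that every code path is exercised, small
enough that the whole suite replays in about a minute.

## Known limitations

* The rule language excludes full OWL-DL features (property chains,
  cardinality, nominals); satisfiability checking is limited to
  disjointness conflicts.
* Intent matching is lexical; paraphrases far from the sample
  utterances fall to clarification. This mirrors the failure mode the
  evaluation measures.
* The EER equations need anthropometrics the profile may not carry;
  reference values are a stated approximation.
* External vocabularies (UMLS, SNOMED CT, ICD-10, DrugBank) and live
  FoodData Central records are not integrated; the ontology is a
  faithful-in-spirit reconstruction at fixture scale.
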