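# dietassist

A text-mode, knowledge-based conversational diet assistant for informal
caregivers of people with Alzheimer disease and related dementias (ADRD).
Good nutrition is one of the few levers caregivers control that can slow
ADRD progression, but the guidelines are scattered and hard to apply to a
specific patient. `dietassist` packages that knowledge as a working
back end: an ontology-style knowledge base, a backward-chaining rule
engine, citable diet-guideline constraints, a finite-state dialogue
manager, personalized recommendation services, and an evaluation harness
for scripted conversations. Everything runs offline from a deterministic
synthetic fixture generator.

## The model in brief

**Knowledge base.** Classes linked by IS-A (subsumption) with
individuals attached by *type*, split into a TBox (class axioms) and
ABox (instances): `partition_kb()` / `merge_kb()` round-trip losslessly.
Food items carry per-100 g nutrients in FoodData Central layout; recipes
are ingredient-gram compositions.

**Inference.** Rules are safe function-free Horn clauses (a Datalog
subset of SWRL) with numeric comparison and arithmetic built-ins and
stratified negation. `prove()` answers goals by tabled backward
chaining: only predicates reachable from the goal are saturated, answer
tables memoize repeated subgoals (so cyclic rule graphs terminate), and
every conclusion keeps the rule and ground subgoals that derived it, so
proofs carry traces. On these programs the procedure computes exactly
the forward-chaining least fixpoint, which is how it is tested.

**Guidelines.** The MIND diet encourage list (vegetables, berries, nuts,
olive oil, whole grains, fish, beans, poultry) and limit list (butter,
margarine, cheese, red meat, fried food, pastries, sweets); the HHS
per-meal target of 800-850 kcal for a man on three meals a day; the ADA
diabetic rules (dinner = 25% of the Estimated Energy Requirement,
protein 20-30% of meal energy, sugar < 10% of meal energy, shares via
Atwater factors 4/4/9 kcal/g). `check_meal_constraints()` returns one
violation record per failed check, each citing its guideline.

**Dialogue.** Utterances are lowercased, expanded with ontology
synonyms, and scored against intent sample utterances by Jaccard token
overlap (threshold 0.5). Each of the five service categories (diet
tips, eating challenges, food explanation, meal suggestion, history
recall) has a finite-state graph from `S0`; slots are elicited one per
turn with over-answering and profile prefill; short-term context expires
after 5 turns; responses are rendered per caregiver education tier.

**Evaluation.** `run_script()` replays JSONL conversations; a dialogue
succeeds if a satisfying response arrives within 20 turns (Eq.-style
`success_rate()` = 100·n/N) and every substantive response is re-judged
for guideline/profile consistency (`correctness_rate()`).

## Worked example

```r
library(dietassist)

dir <- file.path(tempdir(), "bundle")
generate_fixture_bundle(fixture_spec(seed = 1), dir)
fx <- load_fixture_app(dir)

patient  <- fx$profiles$patients$father     # 65, early ADRD, type 2 diabetes, EER 2000
caregiver <- fx$profiles$caregivers$daughter

check_food_suitability("cheese", "snack", patient, fx$kb, fx$app$rules)
#> <verdict> not_recommended
#>   - cheese is on the MIND diet's limit list [MIND diet: limit butter and
#>     margarine, cheese, red meat, fried food, pastries, sweets]

res <- recommend_recipe(list(meal = "dinner"), patient, caregiver,
                        fx$kb, fx$app$rules)
res$recipe$name
#> [1] "baked salmon with brown rice and spinach"
round(recipe_nutrients(res$recipe, fx$kb)[["energy_kcal"]])
#> [1] 500
```

The verdict cites the MIND limit list; the recommended dinner hits the
diabetic target (25% of the 2000 kcal EER = 500 kcal per serving) with
protein and sugar shares inside the ADA bands, within the caregiver's
40-minute and 12-per-meal limits. Replaying the shipped conversation
scripts:

```r
ev <- evaluate_scripts(fx$script_paths, fx$app, fx$profiles)
print(ev)
#> category               dialogues  avg turns       success rate   correctness rate
#> food_explanation              13        2.5      92.3% (12/13)     100.0% (12/12)
#> meal_suggestion               11        3.5      90.9% (10/11)     100.0% (12/12)
#> proper_diet_tips              10        2.9       90.0% (9/10)       100.0% (9/9)
```

The failures are the three deliberately adversarial scripts, each marked
failed at exactly the 20-turn threshold.

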