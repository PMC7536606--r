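test_that("the default registry has exactly the five service categories", {
  registry <- load_intent_registry()
  expect_length(intent_categories(registry), 5L)
  expect_setequal(intent_categories(registry),
                  c("proper_diet_tips", "eating_challenge", "food_explanation",
                    "meal_suggestion", "history_recall"))
  for (it in registry) expect_gte(length(it$utterances), 1L)
})

test_that("intent detection extracts the cheese/snack variables", {
  fx <- fixture_app()
  di <- detect_intent("Is cheddar cheese good as a snack for my dad?",
                      fx$app$registry, fx$app$vocabulary, fx$app$kb)
  expect_equal(di$intent$name, "FoodSuitability")
  expect_equal(di$slots$food, "cheddar_cheese")
  expect_equal(di$slots$meal, "snack")

  # synonym expansion: "cheddar" resolves to the cheese item
  di2 <- detect_intent("is cheddar ok for a snack", fx$app$registry,
                       fx$app$vocabulary, fx$app$kb)
  expect_equal(di2$intent$name, "FoodSuitability")
  expect_equal(di2$slots$food, "cheddar_cheese")

  # gibberish and empty input give no match
  expect_null(detect_intent("blorp zzz", fx$app$registry, fx$app$vocabulary,
                            fx$app$kb))
  expect_null(detect_intent("", fx$app$registry, fx$app$vocabulary, fx$app$kb))

  # deterministic for identical inputs
  expect_identical(
    detect_intent("suggest a dinner recipe", fx$app$registry,
                  fx$app$vocabulary, fx$app$kb),
    detect_intent("suggest a dinner recipe", fx$app$registry,
                  fx$app$vocabulary, fx$app$kb))
})

over_answer_intent <- function() {
  structure(list(
    name = "TestRecipe", category = "meal_suggestion",
    slots = list(
      list(name = "meal", type = "meal_type", required = TRUE,
           prompt = "Which meal?", prefill = NULL),
      list(name = "servings", type = "count", required = TRUE,
           prompt = "How many servings?", prefill = NULL),
      list(name = "max_time", type = "minutes", required = TRUE,
           prompt = "How much time?", prefill = NULL)
    ),
    utterances = "recipe for {meal}"), class = "intent")
}

test_that("slot filling supports over-answering without overwriting", {
  fx <- fixture_app()
  patient <- fx$profiles$patients$father
  caregiver <- fx$profiles$caregivers$daughter
  s <- dialogue_session(patient, caregiver)
  it <- over_answer_intent()
  fill_slots(s, it, list(meal = "dinner"))
  expect_false(dietassist:::slots_complete(s, it))

  # one reply supplies servings and max_time together
  ex <- dietassist:::expand_utterance(tokenize("2 servings and 30 minutes"),
                                      fx$app$vocabulary)
  answers <- list(
    servings = dietassist:::extract_slot_value("count", ex$tokens,
                                               ex$concepts, fx$app$kb),
    max_time = dietassist:::extract_slot_value("minutes", ex$tokens,
                                               ex$concepts, fx$app$kb))
  fill_slots(s, it, answers)
  expect_true(dietassist:::slots_complete(s, it))
  expect_equal(s$slots$servings, 2L)
  expect_equal(s$slots$max_time, 30)

  # a confirmed slot is never overwritten
  fill_slots(s, it, list(meal = "lunch", servings = 5))
  expect_equal(s$slots$meal, "dinner")
  expect_equal(s$slots$servings, 2L)
})

test_that("profile prefill completes slots without elicitation", {
  fx <- fixture_app()
  s <- dialogue_session(fx$profiles$patients$father,
                        fx$profiles$caregivers$daughter)
  it <- over_answer_intent()
  it$slots[[3]]$prefill <- "caregiver.time_limit"
  fill_slots(s, it, list(meal = "dinner", servings = 2))
  expect_true(dietassist:::slots_complete(s, it))
  expect_equal(s$slots$max_time, 40) # from the caregiver profile
})

test_that("state transitions honor declaration order and fall back to a self-loop", {
  graph <- list(
    S0 = list(id = "S0", action = "greet",
              transitions = list(list(when = "intent", to = "S3")),
              terminal = FALSE),
    S3 = list(id = "S3", action = "elicit_slot",
              transitions = list(list(when = "slots_complete", to = "S4"),
                                 list(when = "no_match", to = "S5")),
              terminal = FALSE),
    S4 = list(id = "S4", action = "offer", transitions = list(), terminal = FALSE),
    S5 = list(id = "S5", action = "close", transitions = list(), terminal = TRUE)
  )
  fx <- fixture_app()
  s <- dialogue_session(fx$profiles$patients$father,
                        fx$profiles$caregivers$daughter)
  expect_equal(s$current_state, "S0") # fresh session starts at S0
  expect_equal(s$history[1], "S0")

  s$current_state <- "S3"
  # first matching condition wins: S4 and S5 are both successors of S3
  r1 <- next_state(s, list(kind = "answer", slots_complete = TRUE), graph)
  expect_equal(r1$state, "S4")
  s$current_state <- "S3"
  r2 <- next_state(s, list(kind = "no_match"), graph)
  expect_equal(r2$state, "S5")

  # unmatched input: self-loop with re-prompt
  s$current_state <- "S4"
  r3 <- next_state(s, list(kind = "answer"), graph)
  expect_equal(r3$state, "S4")
  expect_equal(r3$action, "reprompt")

  # corrupted state id: reset to S0
  s$current_state <- "S99"
  r4 <- next_state(s, list(kind = "answer"), graph)
  expect_equal(r4$state, "S0")
})

test_that("short-term context expires and long-term context persists", {
  fx <- fixture_app()
  s <- dialogue_session(fx$profiles$patients$father,
                        fx$profiles$caregivers$daughter)
  context_set(s, "meal_choice", "soup", scope = "short", expires_after = 2)
  expire_context(s)
  expect_equal(context_get(s, "meal_choice"), "soup") # one turn later
  expire_context(s)
  expect_null(context_get(s, "meal_choice"))          # expired
  expect_equal(context_get(s, "patient_allergies"), "Shellfish") # long-term
  n <- length(s$context)
  expire_context(s)
  expect_length(s$context, n) # only long entries remain; stable
})

test_that("responses adapt to the education tier deterministically", {
  payload <- list(recipe = "chicken quinoa bowl", energy_kcal = "500",
                  protein_pct = "25", sugar_pct = "6", prep_time = "35",
                  reason = "meets the dinner target")
  adv <- generate_response("offer_recipe", payload,
                           caregiver_profile(30, 10, "advanced"))
  expect_match(adv, "%")
  expect_match(adv, "500")
  bas <- generate_response("offer_recipe", payload,
                           caregiver_profile(30, 10, "basic"))
  expect_false(grepl("%", bas))
  expect_identical(adv, generate_response("offer_recipe", payload,
                                          caregiver_profile(30, 10, "advanced")))

  expect_error(generate_response("no_such_action", payload,
                                 caregiver_profile(30, 10)),
               class = "dietassist_template_error")
  expect_error(generate_response("offer_recipe", list(),
                                 caregiver_profile(30, 10)),
               class = "dietassist_template_error")
})

test_that("sessions traverse only declared states, starting at S0", {
  fx <- fixture_app()
  graphs <- fx$app$graphs
  declared <- unique(unlist(lapply(graphs, names)))
  for (path in fx$script_paths[seq(1, length(fx$script_paths), by = 4)]) {
    sc <- read_script(path)
    res <- run_script(sc, fx$app, fx$profiles$patients$father,
                      fx$profiles$caregivers$daughter)
    expect_true(all(res$transcript$state %in% declared))
  }
})

test_that("dialogues respect the turn budget", {
  fx <- fixture_app()
  s <- dialogue_session(fx$profiles$patients$father,
                        fx$profiles$caregivers$daughter, max_turns = 5)
  for (i in 1:6) dm_step(fx$app, s, "blorp unintelligible zzz")
  expect_true(s$failed)
})
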