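test_that("food suitability verdicts cite the MIND lists", {
  fx <- fixture_app()
  patient <- fx$profiles$patients$father

  v <- check_food_suitability("cheese", "snack", patient, fx$kb, fx$app$rules)
  expect_equal(v$suitable, "not_recommended")
  expect_match(v$reasons$provenance[1], "MIND diet: limit")

  v2 <- check_food_suitability("berries", "snack", patient, fx$kb, fx$app$rules)
  expect_equal(v2$suitable, "recommended")
  expect_match(v2$reasons$provenance[1], "MIND diet: encourages")

  # verdicts on ABox foods carry an entailment trace through the rule base
  v3 <- check_food_suitability("cheddar_cheese", "snack", patient, fx$kb,
                               fx$app$rules)
  expect_equal(v3$suitable, "not_recommended")
  expect_true("mind.lim.cheese" %in% v3$trace$rule)

  # hard exclusion beats MIND status
  allergic <- diabetic_patient(allergies = "Berries")
  v4 <- check_food_suitability("blueberry", "snack", allergic, fx$kb,
                               fx$app$rules)
  expect_equal(v4$suitable, "not_recommended")
  expect_match(v4$reasons$provenance[1], "allergy")

  expect_error(check_food_suitability("unobtainium", "snack", patient, fx$kb),
               class = "dietassist_lookup_error")
})

test_that("diabetic patients get a sugar caution on sugar-dense foods", {
  fx <- fixture_app()
  v <- check_food_suitability("grapes", "snack", fx$profiles$patients$father,
                              fx$kb, fx$app$rules)
  sugar <- fx$kb$foods$grapes$nutrients[["sugar_g"]]
  if (sugar >= 15) {
    expect_true(any(grepl("sugar", v$reasons$provenance)))
  }
  succeed() # branch coverage depends on the drawn nutrients
})

snack_toy_kb <- function() {
  nut <- function(sugar = 2) c(energy_kcal = 200, protein_g = 8, carb_g = 20,
                               sugar_g = sugar, fat_g = 9, satfat_g = 2,
                               fiber_g = 3, sodium_mg = 50)
  kb_new(
    classes = list(
      ont_class("Food"), ont_class("SnackFood", parents = "Food"),
      ont_class("Nuts", parents = "Food"),
      ont_class("Sweets", parents = "Food"),
      ont_class("Fruits", parents = "Food")
    ),
    individuals = list(individual("nuts_mix", types = "SnackFood"),
                       individual("candy_bar", types = "SnackFood"),
                       individual("apple_x", types = "SnackFood"),
                       individual("banana_x", types = "SnackFood")),
    foods = list(
      food_item("nuts_mix", "nuts mix", "Nuts", nut()),
      food_item("candy_bar", "candy bar", "Sweets", nut(40)),
      food_item("apple_x", "apple x", "Fruits", nut()),
      food_item("banana_x", "banana x", "Fruits", nut())
    )
  )
}

test_that("snack suggestion ranks encouraged snacks first with stable ties", {
  kb <- snack_toy_kb()
  caregiver <- caregiver_profile(30, 10)
  patient <- patient_profile(age = 65, sex = "male")

  res <- suggest_snack(patient, caregiver, kb, rules = list())
  expect_equal(res$food$id, "nuts_mix") # the only MIND-encouraged snack

  # with nuts excluded, the two neutral fruits tie: smaller id wins
  no_nuts <- patient_profile(age = 65, sex = "male", allergies = "Nuts")
  res2 <- suggest_snack(no_nuts, caregiver, kb, rules = list())
  expect_equal(res2$food$id, "apple_x")

  # everything excluded -> empty result with an explanation
  none <- patient_profile(age = 65, sex = "male", allergies = "Food")
  res3 <- suggest_snack(none, caregiver, kb, rules = list())
  expect_null(res3$food)
  expect_gt(nrow(res3$verdict$reasons), 0L)
})

test_that("recipe recommendation matches brute-force admissibility and ranking", {
  fx <- fixture_app()
  patient <- fx$profiles$patients$father
  caregiver <- fx$profiles$caregivers$daughter
  session <- dialogue_session(patient, caregiver)

  # brute force: evaluate every recipe against the full constraint set
  admissible <- sort(names(purrr::keep(fx$kb$recipes, function(r) {
    "dinner" %in% r$meal_types &&
      nrow(check_meal_constraints(r, patient, caregiver, fx$kb,
                                  meal = "dinner")) == 0L
  })))
  expect_equal(admissible, c("d01", "d02"))

  res1 <- recommend_recipe(list(meal = "dinner"), patient, caregiver, fx$kb,
                           fx$app$rules, session)
  expect_true(res1$recipe$id %in% admissible)
  expect_gt(nrow(res1$rationale), 0L)
  expect_true(all(nzchar(res1$rationale$provenance)))

  # ranking oracle: encouraged ingredients desc, energy distance asc, id
  enc <- vapply(admissible, function(id) {
    dietassist:::count_encouraged_ingredients(fx$kb$recipes[[id]], fx$kb)
  }, integer(1))
  dist <- vapply(admissible, function(id) {
    abs(recipe_nutrients(fx$kb$recipes[[id]], fx$kb)[["energy_kcal"]] - 500)
  }, numeric(1))
  expect_equal(res1$recipe$id, admissible[order(-enc, dist, admissible)][1])

  # rejection: the alternative admissible recipe is offered next
  session$rejected <- union(session$rejected, res1$recipe$id)
  res2 <- recommend_recipe(list(meal = "dinner"), patient, caregiver, fx$kb,
                           fx$app$rules, session)
  expect_equal(sort(c(res1$recipe$id, res2$recipe$id)), admissible)

  # both rejected -> none, with the binding constraint explained
  session$rejected <- admissible
  res3 <- recommend_recipe(list(meal = "dinner"), patient, caregiver, fx$kb,
                           fx$app$rules, session)
  expect_null(res3$recipe)
  expect_true(nzchar(res3$reason))

  # a caregiver with no cooking time gets no recommendation
  rushed <- caregiver_profile(time_limit = 1, budget = 12)
  res4 <- recommend_recipe(list(meal = "dinner"), patient, rushed, fx$kb,
                           fx$app$rules)
  expect_null(res4$recipe)

  expect_error(recommend_recipe(list(), patient, caregiver, fx$kb),
               class = "dietassist_validation_error")
})

test_that("diet history records append and recall by day and week", {
  kb <- compliant_dinner_kb()
  h <- NULL
  for (i in 1:3) {
    h <- record_meal(h, meal_record("2026-09-10", c("breakfast", "lunch",
                                                    "dinner")[i], "rx", kb))
  }
  day <- recall_history(h, "day", "2026-09-10")
  expect_equal(nrow(day$records), 3L)
  expect_equal(day$total_energy, sum(h$energy_kcal))

  h2 <- NULL
  for (d in 0:6) {
    h2 <- record_meal(h2, meal_record(as.Date("2026-09-01") + d, "dinner",
                                      "rx", kb))
  }
  week <- recall_history(h2, "week", "2026-09-07")
  expect_equal(nrow(week$records), 7L)

  empty <- recall_history(NULL, "day", "2026-09-10")
  expect_equal(nrow(empty$records), 0L)
  expect_equal(empty$total_energy, 0)

  expect_error(meal_record("not-a-date", "lunch", "rx", kb),
               class = "dietassist_validation_error")
  expect_error(meal_record("2026-09-10", "lunch", "ghost", kb),
               class = "dietassist_lookup_error")

  # JSONL round-trip
  p <- withr::local_tempfile(fileext = ".jsonl")
  write_meal_history(h, p)
  expect_equal(read_meal_history(p)$energy_kcal, h$energy_kcal)
})

test_that("tips match category and stage and cycle deterministically", {
  tips <- load_tip_bank()
  t1 <- get_tip(tips, "eating_challenge", "middle", "standard", cursor = 0)
  matching <- purrr::keep(tips, function(t) t$id == t1$id)[[1]]
  expect_equal(matching$category, "eating_challenge")
  expect_true(any(c("middle", "any") %in% unlist(matching$stages)))

  t2 <- get_tip(tips, "eating_challenge", "middle", "standard", cursor = 1)
  expect_false(identical(t1$id, t2$id)) # >= 2 matching tips cycle

  expect_error(get_tip(tips, "astrology", "early"),
               class = "dietassist_validation_error")
  suppressWarnings(expect_error(load_tip_bank(withr::local_tempfile(fileext = ".yaml"))))
})
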