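test_that("mind_classify follows the encourage/limit lists through IS-A", {
  kb <- fixture_app()$kb
  expect_equal(mind_classify(kb, "berries"), "encourage")
  expect_equal(mind_classify(kb, "cheese"), "limit")
  expect_equal(mind_classify(kb, "water"), "neutral")

  # inheritance: a food inherits its listed ancestor's classification
  expect_equal(mind_classify(kb, "blueberry"), "encourage")   # IS-A Berries
  expect_equal(mind_classify(kb, "cheddar_cheese"), "limit")  # IS-A Cheese
  expect_equal(mind_classify(kb, "yogurt"), "neutral")        # Dairy, unlisted

  # limit wins when a concept matches both lists
  kb2 <- kb_new(classes = list(
    ont_class("Food"), ont_class("Nuts", parents = "Food"),
    ont_class("Sweets", parents = "Food"),
    ont_class("CandiedNuts", parents = c("Nuts", "Sweets"))
  ))
  expect_equal(mind_classify(kb2, "CandiedNuts"), "limit")

  expect_error(mind_classify(kb, "unobtainium"),
               class = "dietassist_lookup_error")
})

test_that("meal calorie targets follow HHS, ADA, and the EER fallback", {
  hhs <- patient_profile(age = 70, sex = "male", meals_per_day = 3)
  t1 <- meal_calorie_target(hhs, "lunch")
  expect_equal(as.numeric(t1), c(800, 850))
  expect_match(attr(t1, "provenance"), "800-850")

  dia <- diabetic_patient()
  t2 <- meal_calorie_target(dia, "dinner")
  expect_equal(as.numeric(t2), c(500, 500)) # 25% of EER 2000
  expect_match(attr(t2, "provenance"), "25%")

  # diabetic dinner without an EER must ask for it
  dia_noeer <- patient_profile(age = 65, sex = "male",
                               comorbidities = "type2_diabetes")
  expect_error(meal_calorie_target(dia_noeer, "dinner"),
               class = "dietassist_missing_data_error")

  # everyone else: EER split across meals, +/-10%
  fem <- patient_profile(age = 80, sex = "female", eer = 1800,
                         meals_per_day = 4)
  t3 <- meal_calorie_target(fem, "breakfast")
  expect_equal(as.numeric(t3), c(0.9, 1.1) * 1800 / 4)
})

test_that("estimate_eer prefers the stored value and falls back to the equations", {
  expect_equal(estimate_eer(diabetic_patient()), 2000)
  p <- patient_profile(age = 65, sex = "male", weight_kg = 77, height_m = 1.76)
  expect_equal(estimate_eer(p),
               662 - 9.53 * 65 + 1.11 * (15.91 * 77 + 539.6 * 1.76))
})

test_that("a hand-built compliant diabetic dinner passes every constraint", {
  kb <- compliant_dinner_kb()
  patient <- diabetic_patient()
  caregiver <- caregiver_profile(time_limit = 40, budget = 12)
  v <- check_meal_constraints(kb$recipes$rx, patient, caregiver, kb,
                              meal = "dinner")
  expect_equal(nrow(v), 0L)

  nut <- recipe_nutrients(kb$recipes$rx, kb)
  expect_equal(unname(nut[["energy_kcal"]]), 510)
  expect_equal(unname(100 * 4 * nut[["protein_g"]] / nut[["energy_kcal"]]), 25)
  expect_equal(unname(100 * 4 * nut[["sugar_g"]] / nut[["energy_kcal"]]), 6)
})

test_that("each violated constraint is reported with provenance", {
  kb <- compliant_dinner_kb()
  patient <- diabetic_patient()
  caregiver <- caregiver_profile(time_limit = 40, budget = 12)

  # sugar at 12% of energy -> sugar violation naming the 10% bound
  kb_sugar <- kb
  kb_sugar$foods$plated_dinner$nutrients["sugar_g"] <- 0.12 * 510 / 4
  v <- check_meal_constraints(kb_sugar$recipes$rx, patient, caregiver,
                              kb_sugar, meal = "dinner")
  expect_equal(v$constraint, "sugar_share")
  expect_match(v$bound, "10%")
  expect_true(all(nzchar(v$provenance)))

  # allergy matched via an IS-A ancestor class
  allergic <- diabetic_patient(allergies = "Fish")
  v2 <- check_meal_constraints(kb$recipes$rx, allergic, caregiver, kb,
                               meal = "dinner")
  expect_true("allergy" %in% v2$constraint)

  # caregiver limits
  rushed <- caregiver_profile(time_limit = 10, budget = 1)
  v3 <- check_meal_constraints(kb$recipes$rx, patient, rushed, kb,
                               meal = "dinner")
  expect_setequal(v3$constraint, c("prep_time", "budget"))
})

test_that("every violation provenance string is present in the rule file", {
  rules <- default_guideline_rules()
  rule_prov <- unique(vapply(rules, function(r) r$provenance, character(1)))
  expect_true(all(unlist(dietassist:::guideline_provenance) %in% rule_prov))
})

test_that("tabulated energy stays within the Atwater sanity band", {
  kb <- fixture_app()$kb
  for (f in kb$foods) {
    derived <- 4 * f$nutrients[["protein_g"]] + 4 * f$nutrients[["carb_g"]] +
      9 * f$nutrients[["fat_g"]]
    if (derived == 0) next # water-like items carry no energy
    expect_lt(abs(f$nutrients[["energy_kcal"]] - derived) / derived, 0.3)
  }
})

test_that("constraint checking agrees with the generator's manifest arithmetic", {
  fx <- fixture_app()
  patient <- fx$profiles$patients$father
  caregiver <- fx$profiles$caregivers$daughter
  for (m in fx$manifest$recipes) {
    if (!"dinner" %in% unlist(m$meal_types)) next
    v <- check_meal_constraints(fx$kb$recipes[[m$id]], patient, caregiver,
                                fx$kb, meal = "dinner")
    expect_equal(nrow(v) == 0L, isTRUE(m$admissible_for_persona), info = m$id)
    map_to_checker <- c(calorie = "calorie_target", protein = "protein_share",
                        sugar = "sugar_share", allergy = "allergy",
                        time = "prep_time", budget = "budget")
    expect_setequal(unique(v$constraint),
                    unname(map_to_checker[unlist(m$dinner_violations)]))
  }
})
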