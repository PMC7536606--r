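#' Deterministic synthetic fixtures
#'
#' Generates every input the assistant consumes, offline and
#' reproducibly: a food composition table emulating FoodData Central
#' structure, the food/diet ontology fragment, recipes with controlled
#' macro profiles, patient/caregiver profiles (including the reference
#' persona: a female caregiver looking after her 65-year-old father in
#' early-stage ADRD with type 2 diabetes), and JSONL conversation
#' scripts for the three evaluated service categories. A fixed seed
#' yields byte-identical artifacts.
#'
#' Nutrient values are drawn per food category from plausible per-100 g
#' ranges; energy is derived from the drawn macros by Atwater factors
#' (4/4/9) with a small multiplicative jitter, so tabulated energy and
#' macro-derived energy always agree to well within 30%.
#'
#' @name fixtures
NULL

#' Fixture generation settings
#'
#' @param seed Integer RNG seed; fixed seed implies byte-identical
#'   outputs.
#' @param n_foods Number of foods (>= the 16 mandatory categories).
#' @param n_recipes Number of recipes (the first 20 are the designed
#'   set; more are not supported).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_foods = 50L, n_recipes = 20L) {
  if (!is_count(seed, 0)) da_abort("seed must be a non-negative integer",
                                   "dietassist_validation_error")
  structure(list(seed = as.integer(seed), n_foods = as.integer(n_foods),
                 n_recipes = as.integer(n_recipes)),
            class = "fixture_spec")
}

# ---- ontology ----------------------------------------------------------------

fixture_classes <- function() {
  c1 <- function(...) ont_class(...)
  list(
    c1("Food", label = "food"),
    c1("Vegetables", label = "vegetables", parents = "Food",
       synonyms = c("veggies", "vegetable")),
    c1("Fruits", label = "fruits", parents = "Food", synonyms = "fruit"),
    c1("Berries", label = "berries", parents = "Fruits", synonyms = "berry"),
    c1("Nuts", label = "nuts", parents = "Food"),
    c1("Oils", label = "oils", parents = "Food"),
    c1("OliveOil", label = "olive oil", parents = "Oils"),
    c1("Grains", label = "grains", parents = "Food"),
    c1("WholeGrains", label = "whole grains", parents = "Grains"),
    c1("BakedGoods", label = "baked goods", parents = "Food"),
    c1("Pastries", label = "pastries", parents = "BakedGoods",
       synonyms = "pastry"),
    c1("Seafood", label = "seafood", parents = "Food"),
    c1("Fish", label = "fish", parents = "Seafood"),
    c1("Shellfish", label = "shellfish", parents = "Seafood"),
    c1("Legumes", label = "legumes", parents = "Food"),
    c1("Beans", label = "beans", parents = "Legumes"),
    c1("Meat", label = "meat", parents = "Food"),
    c1("Poultry", label = "poultry", parents = "Meat"),
    c1("RedMeat", label = "red meat", parents = "Meat"),
    c1("Dairy", label = "dairy", parents = "Food"),
    c1("Cheese", label = "cheese", parents = "Dairy"),
    c1("Butter", label = "butter spread", parents = "Dairy"),
    c1("Spreads", label = "spreads", parents = "Food"),
    c1("Margarine", label = "margarine", parents = "Spreads"),
    c1("FriedFood", label = "fried food", parents = "Food"),
    c1("Sweets", label = "sweets", parents = "Food",
       synonyms = c("desserts", "dessert")),
    c1("Beverages", label = "beverages", parents = "Food"),
    c1("SnackFood", label = "snack food", parents = "Food"),
    c1("Condition", label = "condition"),
    c1("Diabetes", label = "diabetes", parents = "Condition",
       synonyms = "type 2 diabetes"),
    c1("Dementia", label = "dementia", parents = "Condition",
       synonyms = "alzheimer")
  )
}

# name, category, synonyms; ordered so the mandatory MIND categories
# (8 encourage + 7 limit) plus Shellfish come first
fixture_food_pool <- function() {
  f <- function(name, category, syn = character(), id = food_id_of(name)) {
    list(name = name, category = category, syn = syn, id = id)
  }
  list(
    f("spinach", "Vegetables"),
    f("blueberry", "Berries", "blueberries"),
    f("almonds", "Nuts", "almond"),
    f("extra virgin olive oil", "OliveOil", id = "olive_oil"),
    f("brown rice", "WholeGrains", "whole grain rice"),
    f("salmon", "Fish", "atlantic salmon"),
    f("lentils", "Beans"),
    f("chicken breast", "Poultry", "chicken"),
    f("butter", "Butter"),
    f("soft margarine", "Margarine", id = "margarine"),
    f("cheddar cheese", "Cheese", "cheddar"),
    f("beef steak", "RedMeat", c("beef", "steak")),
    f("french fries", "FriedFood", c("fries", "chips")),
    f("croissant", "Pastries"),
    f("milk chocolate", "Sweets", "chocolate"),
    f("shrimp", "Shellfish", "prawns"),
    f("water", "Beverages", "drinking water"),
    f("quinoa", "WholeGrains"),
    f("broccoli", "Vegetables"),
    f("carrot", "Vegetables", "carrots"),
    f("kale", "Vegetables"),
    f("tomato", "Vegetables", "tomatoes"),
    f("strawberry", "Berries", "strawberries"),
    f("raspberry", "Berries"),
    f("walnuts", "Nuts", "walnut"),
    f("oatmeal", "WholeGrains", c("oats", "porridge")),
    f("whole wheat bread", "WholeGrains", "wholemeal bread"),
    f("tuna", "Fish"),
    f("cod", "Fish"),
    f("sardines", "Fish"),
    f("black beans", "Beans"),
    f("chickpeas", "Beans"),
    f("turkey breast", "Poultry", "turkey"),
    f("mozzarella", "Cheese"),
    f("pork chop", "RedMeat", "pork"),
    f("lamb", "RedMeat"),
    f("fried chicken", "FriedFood"),
    f("danish pastry", "Pastries"),
    f("cookies", "Sweets", "biscuits"),
    f("ice cream", "Sweets"),
    f("apple", "Fruits", "apples"),
    f("banana", "Fruits", "bananas"),
    f("orange", "Fruits", "oranges"),
    f("grapes", "Fruits"),
    f("yogurt", "Dairy", "yoghurt"),
    f("milk", "Dairy"),
    f("cauliflower", "Vegetables"),
    f("green peas", "Vegetables", "peas"),
    f("cucumber", "Vegetables"),
    f("blackberry", "Berries")
  )
}

snackable_categories <- c("Berries", "Nuts", "Cheese", "Sweets", "Fruits")

# per-category nutrient ranges per 100 g: protein/carb/fat/fiber in g,
# sugar and saturated fat as fractions, sodium in mg
nutrient_ranges <- list(
  Vegetables = list(p = c(1, 3), c = c(4, 10), sf = c(0.2, 0.5),
                    f = c(0.1, 0.6), sa = c(0.1, 0.2), fi = c(1.5, 4),
                    na = c(10, 80)),
  Berries = list(p = c(0.5, 1.5), c = c(8, 15), sf = c(0.5, 0.7),
                 f = c(0.2, 0.6), sa = c(0.05, 0.1), fi = c(2, 6),
                 na = c(1, 5)),
  Fruits = list(p = c(0.3, 1.2), c = c(12, 22), sf = c(0.6, 0.8),
                f = c(0.1, 0.4), sa = c(0.1, 0.2), fi = c(1.5, 3.5),
                na = c(1, 5)),
  Nuts = list(p = c(15, 25), c = c(15, 25), sf = c(0.15, 0.3),
              f = c(45, 60), sa = c(0.08, 0.15), fi = c(6, 11), na = c(1, 10)),
  OliveOil = list(p = c(0, 0), c = c(0, 0), sf = c(0, 0), f = c(99, 100),
                  sa = c(0.13, 0.15), fi = c(0, 0), na = c(0, 2)),
  WholeGrains = list(p = c(3, 7), c = c(20, 30), sf = c(0.01, 0.05),
                     f = c(1, 3), sa = c(0.15, 0.25), fi = c(2, 5),
                     na = c(1, 10)),
  Fish = list(p = c(18, 25), c = c(0, 0.5), sf = c(0, 0), f = c(2, 13),
              sa = c(0.2, 0.3), fi = c(0, 0), na = c(40, 110)),
  Shellfish = list(p = c(18, 24), c = c(0, 1), sf = c(0, 0), f = c(0.5, 2),
                   sa = c(0.2, 0.3), fi = c(0, 0), na = c(100, 300)),
  Beans = list(p = c(7, 10), c = c(15, 25), sf = c(0.05, 0.15),
               f = c(0.3, 1.5), sa = c(0.1, 0.2), fi = c(6, 9), na = c(1, 10)),
  Poultry = list(p = c(22, 30), c = c(0, 0.5), sf = c(0, 0), f = c(2, 8),
                 sa = c(0.25, 0.35), fi = c(0, 0), na = c(50, 90)),
  Butter = list(p = c(0.5, 1), c = c(0, 1), sf = c(0.5, 0.9), f = c(80, 83),
                sa = c(0.6, 0.68), fi = c(0, 0), na = c(500, 700)),
  Margarine = list(p = c(0.1, 0.5), c = c(0, 1), sf = c(0, 0.5),
                   f = c(60, 80), sa = c(0.2, 0.3), fi = c(0, 0),
                   na = c(600, 800)),
  Cheese = list(p = c(20, 26), c = c(1, 3), sf = c(0.3, 0.6), f = c(25, 34),
                sa = c(0.55, 0.65), fi = c(0, 0), na = c(500, 750)),
  RedMeat = list(p = c(20, 27), c = c(0, 0.5), sf = c(0, 0), f = c(10, 22),
                 sa = c(0.35, 0.45), fi = c(0, 0), na = c(50, 80)),
  FriedFood = list(p = c(3, 15), c = c(25, 40), sf = c(0, 0.1),
                   f = c(12, 20), sa = c(0.2, 0.35), fi = c(2, 4),
                   na = c(200, 500)),
  Pastries = list(p = c(5, 8), c = c(40, 55), sf = c(0.2, 0.35),
                  f = c(15, 25), sa = c(0.4, 0.6), fi = c(1, 3),
                  na = c(300, 500)),
  Sweets = list(p = c(4, 7), c = c(55, 65), sf = c(0.7, 0.9), f = c(20, 32),
                sa = c(0.5, 0.65), fi = c(1, 3), na = c(50, 150)),
  Dairy = list(p = c(3.5, 10), c = c(4, 6), sf = c(0.7, 0.9), f = c(1, 5),
               sa = c(0.6, 0.7), fi = c(0, 0), na = c(40, 80)),
  Beverages = list(p = c(0, 0), c = c(0, 0), sf = c(0, 0), f = c(0, 0),
                   sa = c(0, 0), fi = c(0, 0), na = c(0, 5))
)

food_id_of <- function(name) gsub(" ", "_", name)

#' Generate the synthetic food database
#'
#' Draws `n_foods` foods across the MIND categories (at least one per
#' encouraged and limited category), with per-category nutrient ranges
#' and IS-A links to category classes; at least 20% of items carry
#' synonyms. Deterministic under the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @return List with `foods` (food items), `classes` (ontology
#'   classes), and `individuals` (snack-typing individuals).
#' @export
generate_food_db <- function(spec) {
  pool <- fixture_food_pool()
  mandatory <- 16L # 8 encourage + 7 limit + Shellfish
  if (spec$n_foods < mandatory) {
    da_abort(sprintf("n_foods must be >= %d to cover every mandatory category",
                     mandatory), "dietassist_spec_error")
  }
  if (spec$n_foods > length(pool)) {
    extra <- spec$n_foods - length(pool)
    for (k in seq_len(extra)) {
      base <- pool[[((k - 1L) %% length(fixture_food_pool())) + 1L]]
      nm <- sprintf("%s variant %d", base$name, k)
      pool[[length(pool) + 1L]] <- list(name = nm, category = base$category,
                                        syn = character(), id = food_id_of(nm))
    }
  }
  pool <- pool[seq_len(spec$n_foods)]
  set.seed(spec$seed)
  draw <- function(rng) stats::runif(1, rng[1], rng[2])
  foods <- map(pool, function(it) {
    rg <- nutrient_ranges[[it$category]]
    p <- draw(rg$p); cb <- draw(rg$c); f <- draw(rg$f)
    sugar <- cb * draw(rg$sf)
    satfat <- f * draw(rg$sa)
    fiber <- draw(rg$fi); na <- draw(rg$na)
    energy <- (4 * p + 4 * cb + 9 * f) * stats::runif(1, 0.95, 1.05)
    food_item(
      id = it$id, name = it$name, category = it$category,
      nutrients = round(c(energy_kcal = energy, protein_g = p, carb_g = cb,
                          sugar_g = sugar, fat_g = f, satfat_g = satfat,
                          fiber_g = fiber, sodium_mg = na), 2),
      synonyms = it$syn
    )
  })
  individuals <- map(
    keep(foods, ~ .x$category %in% snackable_categories),
    ~ individual(.x$id, types = "SnackFood")
  )
  list(foods = foods, classes = fixture_classes(), individuals = individuals)
}

# ---- profiles ----------------------------------------------------------------

#' The reference persona and a secondary profile pair
#'
#' The primary persona is the reference household: a female caregiver
#' cooking for her 65-year-old father, early-stage ADRD with type 2
#' diabetes, EER 2000 kcal/day, shellfish allergy; the caregiver has 40
#' minutes to cook, a 12-per-meal budget, and an advanced education
#' tier. A secondary non-diabetic couple exercises the HHS branch.
#'
#' @return List with `patients` and `caregivers` (named lists).
#' @export
fixture_profiles <- function() {
  list(
    patients = list(
      father = patient_profile(
        id = "father", age = 65, sex = "male", adrd_stage = "early",
        comorbidities = "type2_diabetes", allergies = "Shellfish",
        dislikes = "pork_chop", preferences = "mediterranean",
        eer = 2000, meals_per_day = 3),
      uncle = patient_profile(
        id = "uncle", age = 72, sex = "male", adrd_stage = "middle",
        meals_per_day = 3)
    ),
    caregivers = list(
      daughter = caregiver_profile(id = "daughter", time_limit = 40,
                                   budget = 12, education_level = "advanced"),
      neighbor = caregiver_profile(id = "neighbor", time_limit = 30,
                                   budget = 8, education_level = "basic")
    )
  )
}

# ---- recipes -----------------------------------------------------------------

kb_for_foods <- function(db) {
  kb_new(classes = db$classes, individuals = db$individuals, foods = db$foods)
}

per_serving <- function(ingredients, grams, foods) {
  tot <- stats::setNames(rep(0, length(nutrient_fields)), nutrient_fields)
  for (i in seq_along(ingredients)) {
    tot <- tot + foods[[ingredients[i]]]$nutrients * grams[i] / 100
  }
  tot
}

# deterministically adjust per-serving gram amounts until the meal hits
# the diabetic-dinner band (energy ~target, protein 20-30% of energy,
# sugar < 10%); protein_idx names the ingredient to scale for protein
tune_composition <- function(ingredients, grams, foods, target_kcal,
                             protein_idx) {
  for (iter in 1:60) {
    nut <- per_serving(ingredients, grams, foods)
    e <- nut[["energy_kcal"]]
    if (abs(e - target_kcal) > 0.02 * target_kcal) {
      grams <- grams * target_kcal / e
      next
    }
    pshare <- 100 * 4 * nut[["protein_g"]] / e
    sshare <- 100 * 4 * nut[["sugar_g"]] / e
    if (pshare < 21) { grams[protein_idx] <- grams[protein_idx] * 1.12; next }
    if (pshare > 29) { grams[protein_idx] <- grams[protein_idx] * 0.9; next }
    if (sshare >= 9) {
      sweets <- which.max(map_dbl(ingredients,
                                  ~ foods[[.x]]$nutrients[["sugar_g"]]))
      grams[sweets] <- grams[sweets] * 0.8
      next
    }
    return(round(grams, 1))
  }
  da_abort("could not tune a compliant composition from the drawn nutrients",
           "dietassist_spec_error")
}

# scale grams so per-serving energy lands on target (no macro tuning)
scale_energy <- function(ingredients, grams, foods, target_kcal) {
  e <- per_serving(ingredients, grams, foods)[["energy_kcal"]]
  round(grams * target_kcal / e, 1)
}

#' Generate the synthetic recipe set
#'
#' Builds 20 recipes with controlled macro profiles. By construction,
#' for the diabetic-dinner persona (EER 2000, so a 500 kcal +/- 5%
#' dinner target): exactly two dinner recipes are admissible, and one
#' dinner recipe violates each constraint class (sugar share, protein
#' share, calorie target, preparation time, budget, allergy). The
#' returned manifest lists, for every recipe, the dinner-constraint
#' violations computed by the generator's own arithmetic.
#'
#' @param spec A [fixture_spec()].
#' @param db Output of [generate_food_db()].
#' @return List with `recipes` and `manifest` (list, one entry per
#'   recipe).
#' @export
generate_recipes <- function(spec, db) {
  if (spec$n_recipes == 0L) {
    return(list(recipes = list(), manifest = list()))
  }
  if (spec$n_recipes != 20L) {
    da_abort("the designed recipe set has exactly 20 recipes",
             "dietassist_spec_error")
  }
  foods <- stats::setNames(db$foods, map_chr(db$foods, "id"))
  need <- c("salmon", "brown_rice", "spinach", "olive_oil", "chicken_breast",
            "quinoa", "broccoli", "shrimp", "milk_chocolate", "beef_steak",
            "french_fries", "butter", "carrot", "lamb", "ice_cream",
            "oatmeal", "blueberry", "milk", "yogurt", "strawberry", "walnuts",
            "whole_wheat_bread", "lentils", "tomato", "tuna", "cucumber",
            "chickpeas", "turkey_breast", "cheddar_cheese", "almonds",
            "grapes", "banana", "apple")
  missing <- setdiff(need, names(foods))
  if (length(missing)) {
    da_abort(sprintf("recipe construction needs food(s) absent from the table: %s",
                     paste(missing, collapse = ", ")),
             "dietassist_spec_error")
  }
  target <- 500 # 25% of the persona's 2000 kcal EER

  mk <- function(id, name, ing, grams, servings, prep, cost, meals) {
    recipe(id = id, name = name,
           ingredients = tibble(food_id = ing, grams = grams * servings),
           servings = servings, prep_time = prep, cost = cost,
           meal_types = meals)
  }

  recipes <- list()

  # two admissible diabetic dinners
  ing1 <- c("salmon", "brown_rice", "spinach", "olive_oil")
  g1 <- tune_composition(ing1, c(120, 150, 100, 7), foods, target, 1L)
  recipes$d01 <- mk("d01", "baked salmon with brown rice and spinach",
                    ing1, g1, 2L, 25, 19, "dinner")
  ing2 <- c("chicken_breast", "quinoa", "broccoli", "olive_oil")
  g2 <- tune_composition(ing2, c(110, 150, 120, 7), foods, target, 1L)
  recipes$d02 <- mk("d02", "chicken quinoa bowl with broccoli",
                    ing2, g2, 2L, 35, 16, "dinner")

  # one violator per constraint class
  ing3 <- c("salmon", "brown_rice", "ice_cream")
  g3 <- scale_energy(ing3, c(90, 110, 90), foods, target)
  recipes$d03 <- mk("d03", "salmon rice bowl with ice cream dessert",
                    ing3, g3, 2L, 30, 18, "dinner") # sugar violator
  ing4 <- c("brown_rice", "carrot", "butter")
  g4 <- scale_energy(ing4, c(220, 120, 18), foods, target)
  recipes$d04 <- mk("d04", "buttered rice with carrots",
                    ing4, g4, 2L, 20, 8, "dinner") # protein violator
  ing5 <- c("beef_steak", "french_fries", "butter")
  recipes$d05 <- mk("d05", "hearty steak and fries platter",
                    ing5, c(250, 220, 15), 2L, 30, 22, "dinner") # calories
  ing6 <- c("lamb", "brown_rice", "carrot", "olive_oil")
  g6 <- tune_composition(ing6, c(110, 130, 100, 6), foods, target, 1L)
  recipes$d06 <- mk("d06", "slow-braised lamb with rice",
                    ing6, g6, 2L, 90, 20, "dinner") # time violator
  ing7 <- c("beef_steak", "quinoa", "spinach", "olive_oil")
  g7 <- tune_composition(ing7, c(110, 130, 100, 6), foods, target, 1L)
  recipes$d07 <- mk("d07", "premium beef tenderloin dinner",
                    ing7, g7, 2L, 35, 44, "dinner") # budget violator
  ing8 <- c("shrimp", "brown_rice", "olive_oil")
  g8 <- tune_composition(ing8, c(140, 150, 8), foods, target, 1L)
  recipes$d08 <- mk("d08", "garlic shrimp with rice",
                    ing8, g8, 2L, 25, 18, "dinner") # allergy violator

  # breakfasts, lunches, snacks
  recipes$b01 <- mk("b01", "blueberry oatmeal with milk",
                    c("oatmeal", "blueberry", "milk"), c(60, 80, 150),
                    2L, 10, 5, "breakfast")
  recipes$b02 <- mk("b02", "yogurt parfait with strawberries and walnuts",
                    c("yogurt", "strawberry", "walnuts"), c(200, 80, 20),
                    2L, 5, 6, c("breakfast", "snack"))
  recipes$b03 <- mk("b03", "whole wheat toast with butter",
                    c("whole_wheat_bread", "butter"), c(80, 12),
                    2L, 5, 3, "breakfast")
  recipes$l01 <- mk("l01", "lentil vegetable soup",
                    c("lentils", "carrot", "tomato", "olive_oil"),
                    c(120, 80, 80, 5), 4L, 35, 10, "lunch")
  recipes$l02 <- mk("l02", "tuna salad with tomato and cucumber",
                    c("tuna", "tomato", "cucumber", "olive_oil"),
                    c(100, 100, 80, 7), 2L, 15, 9, "lunch")
  recipes$l03 <- mk("l03", "chickpea salad bowl",
                    c("chickpeas", "tomato", "cucumber", "olive_oil"),
                    c(150, 80, 80, 7), 2L, 15, 7, "lunch")
  recipes$l04 <- mk("l04", "turkey sandwich on whole wheat",
                    c("turkey_breast", "whole_wheat_bread", "tomato"),
                    c(80, 80, 50), 2L, 10, 7, "lunch")
  recipes$l05 <- mk("l05", "grilled cheese sandwich",
                    c("cheddar_cheese", "whole_wheat_bread", "butter"),
                    c(60, 80, 10), 2L, 12, 6, "lunch")
  recipes$s01 <- mk("s01", "almond and grape snack cup",
                    c("almonds", "grapes"), c(30, 60), 2L, 3, 4, "snack")
  recipes$s02 <- mk("s02", "apple and walnut plate",
                    c("apple", "walnuts"), c(120, 20), 2L, 3, 3, "snack")
  recipes$s03 <- mk("s03", "banana oat bites",
                    c("banana", "oatmeal"), c(60, 40), 2L, 20, 3, "snack")
  recipes$s04 <- mk("s04", "berry fruit salad",
                    c("blueberry", "strawberry", "banana"), c(60, 60, 50),
                    2L, 5, 5, "snack")

  manifest <- map(recipes, recipe_manifest_entry, foods = foods,
                  target = target)
  list(recipes = unname(recipes), manifest = unname(manifest))
}

# generator-side admissibility arithmetic for the diabetic-dinner
# persona (independent restatement of the guideline thresholds)
recipe_manifest_entry <- function(r, foods, target) {
  nut <- per_serving(r$ingredients$food_id, r$ingredients$grams, foods) /
    r$servings
  e <- nut[["energy_kcal"]]
  violations <- character()
  if ("dinner" %in% r$meal_types) {
    if (e < 0.95 * target || e > 1.05 * target) violations <- c(violations, "calorie")
    if (e > 0) {
      pshare <- 100 * 4 * nut[["protein_g"]] / e
      sshare <- 100 * 4 * nut[["sugar_g"]] / e
      if (pshare < 20 || pshare > 30) violations <- c(violations, "protein")
      if (sshare >= 10) violations <- c(violations, "sugar")
    }
    cats <- map_chr(r$ingredients$food_id, ~ foods[[.x]]$category)
    if ("Shellfish" %in% cats) violations <- c(violations, "allergy")
    if (r$prep_time > 40) violations <- c(violations, "time")
    if (r$cost / r$servings > 12) violations <- c(violations, "budget")
  }
  list(id = r$id, meal_types = as.list(r$meal_types),
       energy_kcal_per_serving = round(e, 1),
       protein_share_pct = if (e > 0) round(100 * 4 * nut[["protein_g"]] / e, 1) else 0,
       sugar_share_pct = if (e > 0) round(100 * 4 * nut[["sugar_g"]] / e, 1) else 0,
       dinner_violations = as.list(violations),
       admissible_for_persona = ("dinner" %in% r$meal_types) &&
         length(violations) == 0L)
}

# ---- conversation scripts ----------------------------------------------------

script_lines <- function(header, users) {
  c(jsonlite::toJSON(header, auto_unbox = TRUE),
    map_chr(users, ~ jsonlite::toJSON(list(user = .x), auto_unbox = TRUE)))
}

#' Generate the JSONL conversation scripts
#'
#' At least ten scripts per evaluated service category (food/nutrition
#' explanation, meal suggestion, proper-diet tips), covering happy
#' paths, slot elicitation, over-answering, rejection-then-alternative,
#' synonym usage, and one adversarial never-terminating script per
#' category (expected to fail at the 20-turn threshold).
#'
#' @param spec A [fixture_spec()].
#' @return Named list: script file name -> character vector of JSONL
#'   lines.
#' @export
generate_scripts <- function(spec) {
  hdr <- function(id, category, success_actions, rep = FALSE) {
    list(id = id, category = category,
         success_actions = as.list(success_actions), `repeat` = rep,
         patient = "father", caregiver = "daughter")
  }
  fe_actions <- c("suitability_verdict", "explain_food")
  ms_actions <- c("offer_recipe", "offer_snack")
  tp_actions <- "tip"
  scripts <- list()

  # food/nutrition explanation
  suit <- list(
    c("blueberry", "snack"), c("butter", "breakfast"), c("salmon", "dinner"),
    c("almonds", "snack"), c("french fries", "lunch"),
    c("milk chocolate", "snack"), c("spinach", "dinner"),
    c("ice cream", "snack"))
  for (i in seq_along(suit)) {
    id <- sprintf("fe_%02d", i)
    scripts[[id]] <- script_lines(
      hdr(id, "food_explanation", fe_actions),
      sprintf("is %s good as a %s for my dad", suit[[i]][1], suit[[i]][2]))
  }
  scripts$fe_09 <- script_lines(
    hdr("fe_09", "food_explanation", fe_actions),
    "is cheddar ok for a snack") # synonym -> cheddar cheese
  scripts$fe_10 <- script_lines(
    hdr("fe_10", "food_explanation", fe_actions),
    c("is cheddar cheese good", "as a snack")) # slot elicitation
  scripts$fe_11 <- script_lines(
    hdr("fe_11", "food_explanation", fe_actions),
    "tell me about walnuts")
  scripts$fe_12 <- script_lines(
    hdr("fe_12", "food_explanation", fe_actions),
    "what nutrients are in oatmeal")
  scripts$fe_adv <- script_lines(
    hdr("fe_adv", "food_explanation", fe_actions, rep = TRUE),
    "blorp zzz frobnicate") # adversarial: never matches

  # meal suggestion
  recipe_openers <- c("recommend a recipe for dinner",
                      "what should i cook for dinner",
                      "suggest a dinner recipe",
                      "i need a recipe for dinner tonight")
  for (i in seq_along(recipe_openers)) {
    id <- sprintf("ms_%02d", i)
    scripts[[id]] <- script_lines(
      hdr(id, "meal_suggestion", ms_actions),
      c(recipe_openers[i], "2 servings", "35 minutes", "yes please"))
  }
  scripts$ms_05 <- script_lines( # over-answering (two slots in one turn)
    hdr("ms_05", "meal_suggestion", ms_actions),
    c("recommend a recipe for dinner", "2 servings and 35 minutes", "yes please"))
  scripts$ms_06 <- script_lines(
    hdr("ms_06", "meal_suggestion", ms_actions),
    c("what should i cook for dinner", "2 servings and 30 minutes", "sounds good"))
  scripts$ms_07 <- script_lines( # rejection then alternative
    hdr("ms_07", "meal_suggestion", ms_actions),
    c("recommend a recipe for dinner", "2 servings and 35 minutes",
      "no something else please", "yes please"))
  scripts$ms_08 <- script_lines(
    hdr("ms_08", "meal_suggestion", ms_actions),
    c("suggest a dinner recipe", "2 servings and 30 minutes",
      "no i would rather have a different one", "ok great"))
  scripts$ms_09 <- script_lines(
    hdr("ms_09", "meal_suggestion", ms_actions),
    "can you suggest a good snack")
  scripts$ms_10 <- script_lines(
    hdr("ms_10", "meal_suggestion", ms_actions),
    c("what is a healthy snack for him", "thanks"))
  scripts$ms_adv <- script_lines( # never supplies the servings slot
    hdr("ms_adv", "meal_suggestion", ms_actions, rep = TRUE),
    c("recommend a recipe for dinner", "hmm let me think about it"))

  # proper-diet tips
  tip_openers <- c("give me a tip on proper diet", "any diet tips for him",
                   "how should he be eating", "share a healthy eating tip",
                   "give me a tip on proper diet please",
                   "any diet tips", "share a healthy eating tip for my dad",
                   "how should he be eating these days",
                   "give me another tip on proper diet")
  for (i in seq_along(tip_openers)) {
    id <- sprintf("tp_%02d", i)
    scripts[[id]] <- script_lines(hdr(id, "proper_diet_tips", tp_actions),
                                  tip_openers[i])
  }
  scripts$tp_adv <- script_lines(
    hdr("tp_adv", "proper_diet_tips", tp_actions, rep = TRUE),
    "wibble wobble nonsense")

  scripts
}

# ---- bundle ------------------------------------------------------------------

#' Generate the complete fixture bundle
#'
#' Writes `foods.csv`, `ontology.json`, `recipes.json`,
#' `profiles.json`, a copy of the guideline rules, per-category script
#' files under `scripts/`, and `manifest.json` into `dir`. Byte
#' deterministic under the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
generate_fixture_bundle <- function(spec = fixture_spec(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "scripts"), showWarnings = FALSE)

  db <- generate_food_db(spec)
  rec <- generate_recipes(spec, db)
  profiles <- fixture_profiles()
  scripts <- generate_scripts(spec)

  paths <- list(
    foods = file.path(dir, "foods.csv"),
    ontology = file.path(dir, "ontology.json"),
    recipes = file.path(dir, "recipes.json"),
    profiles = file.path(dir, "profiles.json"),
    rules = file.path(dir, "guideline_rules.txt"),
    manifest = file.path(dir, "manifest.json")
  )
  write_food_table(db$foods, paths$foods)
  write_ontology_json(db$classes, db$individuals, paths$ontology)
  write_recipes(rec$recipes, paths$recipes)
  write_profiles(profiles$patients, profiles$caregivers, paths$profiles)
  file.copy(system.file("extdata", "guideline_rules.txt",
                        package = "dietassist"),
            paths$rules, overwrite = TRUE)
  for (nm in names(scripts)) {
    p <- file.path(dir, "scripts", paste0(nm, ".jsonl"))
    writeLines(scripts[[nm]], p)
    paths[[paste0("script_", nm)]] <- p
  }
  manifest <- list(
    seed = spec$seed, n_foods = spec$n_foods, n_recipes = spec$n_recipes,
    persona = list(patient = "father", caregiver = "daughter", eer = 2000,
                   dinner_target_kcal = list(475, 525)),
    recipes = rec$manifest,
    n_scripts = length(scripts)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Load a generated fixture bundle into an application
#'
#' @param dir Directory written by [generate_fixture_bundle()].
#' @param ... Passed to [diet_app()].
#' @return List with `app`, `kb`, `profiles`, `manifest`, and
#'   `script_paths`.
#' @export
load_fixture_app <- function(dir, ...) {
  kb <- load_kb(file.path(dir, "foods.csv"), file.path(dir, "recipes.json"),
                file.path(dir, "ontology.json"))
  profiles <- read_profiles(file.path(dir, "profiles.json"))
  rules <- parse_rules(file.path(dir, "guideline_rules.txt"))
  app <- diet_app(kb, rules = rules, ...)
  list(app = app, kb = kb, profiles = profiles,
       manifest = jsonlite::read_json(file.path(dir, "manifest.json")),
       script_paths = sort(list.files(file.path(dir, "scripts"),
                                      full.names = TRUE)))
}
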