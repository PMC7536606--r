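#' Diet guideline knowledge: MIND lists and numeric meal constraints
#'
#' Three citable guideline sources drive personalization:
#'
#' * the MIND diet's encourage list (vegetables, berries, nuts, olive
#'   oil, whole grains, fish, beans, poultry) and limit list (butter,
#'   margarine, cheese, red meat, fried food, pastries, sweets);
#' * the HHS Dietary Guidelines per-meal calorie target of 800-850 kcal
#'   for a man eating three meals per day;
#' * the ADA Diabetes Guidelines: dinner calories at 25% of the
#'   Estimated Energy Requirement, protein at 20-30% of meal energy, and
#'   sugar below 10% of meal energy.
#'
#' Percent-of-energy shares use Atwater factors (4/4/9 kcal per gram of
#' protein/carbohydrate/fat; sugar energy = 4 kcal/g) against the
#' tabulated meal energy.
#'
#' @name guidelines
NULL

mind_encourage_terms <- c("vegetables", "berries", "nuts", "oliveoil",
                          "wholegrains", "fish", "beans", "poultry")
mind_limit_terms <- c("butter", "margarine", "cheese", "redmeat",
                      "friedfood", "pastries", "sweets")

norm_class_term <- function(x) gsub("[^a-z0-9]", "", tolower(x))

# provenance citations; the shipped guideline rule file carries the same
# strings so every violation/verdict reason resolves to a citable rule
guideline_provenance <- list(
  mind_encourage = "MIND diet: encourages vegetables, berries, nuts, olive oil, whole grains, fish, beans, poultry",
  mind_limit = "MIND diet: limit butter and margarine, cheese, red meat, fried food, pastries, sweets",
  hhs_meal = "HHS Dietary Guidelines: one meal should contain 800-850 kcal for a man on three meals per day",
  ada_dinner = "ADA Diabetes Guidelines: dinner total calories 25% of Estimated Energy Requirement",
  ada_protein = "ADA Diabetes Guidelines: protein 20-30% of meal energy",
  ada_sugar = "ADA Diabetes Guidelines: sugar less than 10% of meal energy",
  eer_fallback = "EER-based target: daily energy requirement split evenly across meals, within 10%",
  allergy = "patient profile: allergy exclusion",
  religious = "patient profile: religious constraint",
  dislike = "patient profile: disliked food",
  time = "caregiver profile: cooking time limit",
  budget = "caregiver profile: per-meal budget"
)

#' Load the shipped guideline rule set
#'
#' Parses the guideline rules distributed with the package (SWRL-like
#' plain text, one rule per line with provenance citations). The same
#' knowledge is available as direct constraint functions
#' ([mind_classify()], [meal_calorie_target()],
#' [check_meal_constraints()]); the rule form feeds the inference
#' engine.
#'
#' @param path Rule file; defaults to the packaged
#'   `guideline_rules.txt`.
#' @return List of [horn_rule()]s.
#' @export
default_guideline_rules <- function(path = system.file("extdata", "guideline_rules.txt",
                                                       package = "dietassist")) {
  parse_rules(path)
}

# resolve a surface identifier to a KB concept
# returns list(kind = class|food|individual, id = canonical id) or NULL
resolve_concept <- function(kb, id) {
  if (id %in% names(kb$classes)) return(list(kind = "class", id = id))
  if (id %in% names(kb$foods)) return(list(kind = "food", id = id))
  if (id %in% names(kb$individuals)) return(list(kind = "individual", id = id))
  entries <- synonym_entries(kb)
  hit <- entries$concept[entries$term == norm_term(id)]
  if (length(hit)) {
    return(resolve_concept(kb, sort(hit)[1]))
  }
  NULL
}

# every class the concept belongs to (itself if a class), IS-A closed
concept_ancestry <- function(kb, concept) {
  base <- switch(concept$kind,
    class = concept$id,
    food = {
      f <- kb$foods[[concept$id]]
      union(f$category, kb$individuals[[concept$id]]$types %||% character())
    },
    individual = kb$individuals[[concept$id]]$types
  )
  unique(c(base, unlist(map(base, ~ superclasses(kb, .x)))))
}

#' Classify a food or category under the MIND diet
#'
#' An item is `"encourage"` when it, or any IS-A ancestor, is one of the
#' MIND-encouraged categories, `"limit"` for the limited categories, and
#' `"neutral"` otherwise. If both lists match (e.g. a cheese-topped
#' vegetable category), `"limit"` wins, conservatively.
#'
#' @param kb A `diet_kb`.
#' @param food_or_category A food id, class id, or surface term
#'   resolvable through the KB's synonym table.
#' @return `"encourage"`, `"limit"`, or `"neutral"`.
#' @export
mind_classify <- function(kb, food_or_category) {
  concept <- resolve_concept(kb, food_or_category)
  if (is.null(concept)) {
    da_abort(sprintf("unknown food or category '%s'", food_or_category),
             "dietassist_lookup_error")
  }
  terms <- norm_class_term(concept_ancestry(kb, concept))
  if (any(terms %in% mind_limit_terms)) return("limit")
  if (any(terms %in% mind_encourage_terms)) return("encourage")
  "neutral"
}

#' Per-meal calorie target
#'
#' Resolution order:
#'
#' 1. diabetic patient, dinner: 25% of the profile's EER (degenerate
#'    range; the downstream matching tolerance widens it) -- the EER must
#'    be present, otherwise a missing-data error instructs the dialogue
#'    layer to elicit it;
#' 2. male patient on three meals a day: the HHS 800-850 kcal range;
#' 3. otherwise: EER (stored or estimated) divided by meals per day,
#'    widened by +/-10% (a documented extension beyond the cited
#'    guideline demographics).
#'
#' @param patient A [patient_profile()].
#' @param meal One of `"breakfast"`, `"lunch"`, `"dinner"`, `"snack"`.
#' @return Numeric `c(lo, hi)` in kcal with a `provenance` attribute.
#' @export
meal_calorie_target <- function(patient, meal) {
  meal <- match.arg(meal, meal_type_levels)
  if (has_diabetes(patient) && meal == "dinner") {
    if (is.null(patient$eer)) {
      da_abort("diabetic dinner target needs the patient's EER; please provide it",
               "dietassist_missing_data_error", slot = "eer")
    }
    t <- 0.25 * patient$eer
    return(structure(c(lo = t, hi = t),
                     provenance = guideline_provenance$ada_dinner))
  }
  if (patient$sex == "male" && patient$meals_per_day == 3L &&
      !has_diabetes(patient)) {
    return(structure(c(lo = 800, hi = 850),
                     provenance = guideline_provenance$hhs_meal))
  }
  per_meal <- estimate_eer(patient) / patient$meals_per_day
  structure(c(lo = 0.9 * per_meal, hi = 1.1 * per_meal),
            provenance = guideline_provenance$eer_fallback)
}

#' Per-serving nutrient totals of a recipe
#'
#' Sums each ingredient's per-100 g nutrients scaled by its gram amount
#' and divides by the number of servings.
#'
#' @param recipe A [recipe()].
#' @param kb The KB holding the ingredient foods.
#' @return Named numeric vector over the standard nutrient fields,
#'   per serving.
#' @export
recipe_nutrients <- function(recipe, kb) {
  bad <- setdiff(recipe$ingredients$food_id, names(kb$foods))
  if (length(bad)) {
    da_abort(sprintf("recipe '%s': unresolvable ingredient(s): %s",
                     recipe$id, paste(bad, collapse = ", ")),
             "dietassist_integrity_error")
  }
  tot <- stats::setNames(rep(0, length(nutrient_fields)), nutrient_fields)
  for (i in seq_len(nrow(recipe$ingredients))) {
    f <- kb$foods[[recipe$ingredients$food_id[i]]]
    tot <- tot + f$nutrients * recipe$ingredients$grams[i] / 100
  }
  tot / recipe$servings
}

violation_row <- function(constraint, observed, bound, provenance, detail = "") {
  tibble(constraint = constraint, observed = observed, bound = bound,
         provenance = provenance, detail = detail)
}

no_violations <- function() {
  tibble(constraint = character(), observed = character(), bound = character(),
         provenance = character(), detail = character())
}

fmt_num <- function(x, digits = 1) formatC(x, format = "f", digits = digits)

# TRUE when any of the item's ancestry (or the item itself) intersects
# the exclusion set (ids compared exactly, classes via IS-A closure)
excluded_by <- function(kb, food_id, exclusions) {
  if (length(exclusions) == 0L) return(FALSE)
  concept <- list(kind = "food", id = food_id)
  pool <- c(food_id, concept_ancestry(kb, concept))
  length(intersect(norm_class_term(pool), norm_class_term(exclusions))) > 0L
}

#' Check a recipe against every applicable meal constraint
#'
#' Runs the full personalized constraint set for one meal:
#' calorie target (HHS range, ADA diabetic dinner target, or EER
#' fallback; a recipe matches a degenerate target `t` when within
#' `tolerance` of `t`, and a printed range when inside it), diabetic
#' protein and sugar energy shares, allergy / religious / dislike
#' exclusions (exclusion entries naming a food class exclude all
#' IS-A descendants), preparation time against the caregiver's limit,
#' and per-serving cost against the caregiver's per-meal budget.
#'
#' @param recipe A [recipe()].
#' @param patient A [patient_profile()].
#' @param caregiver A [caregiver_profile()].
#' @param kb The KB.
#' @param meal Meal slot being planned; defaults to the recipe's first
#'   declared meal type.
#' @param tolerance Fractional tolerance around a degenerate calorie
#'   target (default 0.05).
#' @return Tibble of violations (`constraint`, `observed`, `bound`,
#'   `provenance`, `detail`), zero rows iff the recipe is admissible.
#' @export
check_meal_constraints <- function(recipe, patient, caregiver, kb,
                                   meal = NULL, tolerance = 0.05) {
  meal <- meal %||% recipe$meal_types[1]
  meal <- match.arg(meal, meal_type_levels)
  nut <- recipe_nutrients(recipe, kb)
  energy <- nut[["energy_kcal"]]
  out <- no_violations()

  # calorie target
  target <- meal_calorie_target(patient, meal)
  lo <- target[["lo"]]; hi <- target[["hi"]]
  if (lo == hi) {
    lo <- lo * (1 - tolerance)
    hi <- hi * (1 + tolerance)
  }
  if (energy < lo || energy > hi) {
    out <- bind_rows(out, violation_row(
      "calorie_target", fmt_num(energy),
      sprintf("[%s, %s] kcal", fmt_num(lo), fmt_num(hi)),
      attr(target, "provenance"),
      sprintf("per-serving energy %s kcal outside target", fmt_num(energy))))
  }

  # diabetic macro shares (Atwater: protein 4, sugar 4 kcal/g)
  if (has_diabetes(patient) && energy > 0) {
    protein_share <- 100 * 4 * nut[["protein_g"]] / energy
    sugar_share <- 100 * 4 * nut[["sugar_g"]] / energy
    if (protein_share < 20 || protein_share > 30) {
      out <- bind_rows(out, violation_row(
        "protein_share", paste0(fmt_num(protein_share), "%"), "[20%, 30%]",
        guideline_provenance$ada_protein,
        "protein share of meal energy outside the diabetic band"))
    }
    if (sugar_share >= 10) {
      out <- bind_rows(out, violation_row(
        "sugar_share", paste0(fmt_num(sugar_share), "%"), "< 10%",
        guideline_provenance$ada_sugar,
        "sugar share of meal energy at or above the diabetic bound"))
    }
  }

  # hard exclusions (ingredient id, its category, or any IS-A ancestor)
  for (i in seq_len(nrow(recipe$ingredients))) {
    fid <- recipe$ingredients$food_id[i]
    fname <- kb$foods[[fid]]$name
    if (excluded_by(kb, fid, patient$allergies)) {
      out <- bind_rows(out, violation_row(
        "allergy", fname, "must not contain allergen",
        guideline_provenance$allergy,
        sprintf("ingredient '%s' matches a declared allergy", fname)))
    }
    if (excluded_by(kb, fid, patient$religious_constraints)) {
      out <- bind_rows(out, violation_row(
        "religious_constraint", fname, "must not contain excluded food",
        guideline_provenance$religious,
        sprintf("ingredient '%s' is religiously excluded", fname)))
    }
    if (fid %in% patient$dislikes) {
      out <- bind_rows(out, violation_row(
        "dislike", fname, "avoid disliked foods",
        guideline_provenance$dislike,
        sprintf("ingredient '%s' is on the dislike list", fname)))
    }
  }

  # caregiver constraints
  if (recipe$prep_time > caregiver$time_limit) {
    out <- bind_rows(out, violation_row(
      "prep_time", sprintf("%s min", fmt_num(recipe$prep_time, 0)),
      sprintf("<= %s min", fmt_num(caregiver$time_limit, 0)),
      guideline_provenance$time,
      "preparation time exceeds the caregiver's limit"))
  }
  cost_per_meal <- recipe$cost / recipe$servings
  if (cost_per_meal > caregiver$budget) {
    out <- bind_rows(out, violation_row(
      "budget", fmt_num(cost_per_meal, 2),
      sprintf("<= %s per meal", fmt_num(caregiver$budget, 2)),
      guideline_provenance$budget,
      "per-serving cost exceeds the caregiver's budget"))
  }
  out
}
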