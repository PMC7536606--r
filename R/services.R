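#' Personalized diet management services
#'
#' Back-end services answering the dialogue layer's requests: food
#' suitability verdicts, snack suggestion, recipe recommendation with
#' rejection handling, diet-history recording and recall, and tip
#' delivery. Every answer carries reasons citing a guideline provenance
#' string from the rule base.
#'
#' @name services
NULL

verdict <- function(suitable, reasons) {
  stopifnot(suitable %in% c("recommended", "not_recommended", "caution"))
  if (suitable == "not_recommended" && nrow(reasons) == 0L) {
    da_abort("a not_recommended verdict needs at least one reason",
             "dietassist_validation_error")
  }
  structure(list(suitable = suitable, reasons = reasons), class = "diet_verdict")
}

reason_row <- function(provenance, explanation) {
  tibble(provenance = provenance, explanation = explanation)
}

#' @export
print.diet_verdict <- function(x, ...) {
  cat(sprintf("<verdict> %s\n", x$suitable))
  for (i in seq_len(nrow(x$reasons))) {
    cat(sprintf("  - %s [%s]\n", x$reasons$explanation[i], x$reasons$provenance[i]))
  }
  invisible(x)
}

#' @export
tidy.diet_verdict <- function(x, ...) {
  tibble(suitable = x$suitable, x$reasons)
}

#' Is a food suitable for a given meal?
#'
#' Combines hard profile exclusions (allergy, religious constraint,
#' dislike), the MIND classification (proved through the inference
#' engine where the item is an ABox food, so the verdict carries an
#' entailment trace), and comorbidity cautions (for diabetic patients, a
#' high sugar density triggers the ADA sugar rule). For a suitability
#' query a MIND-limited food is `not_recommended`; an encouraged food is
#' `recommended`; anything else is `caution`.
#'
#' @param food Food id, class id, or surface term.
#' @param meal Meal slot asked about.
#' @param patient A [patient_profile()].
#' @param kb The KB.
#' @param rules Guideline rules ([default_guideline_rules()]).
#' @return A `diet_verdict` with at least one cited reason.
#' @export
check_food_suitability <- function(food, meal, patient, kb,
                                   rules = default_guideline_rules()) {
  concept <- resolve_concept(kb, food)
  if (is.null(concept)) {
    da_abort(sprintf("unknown food or category '%s'", food),
             "dietassist_lookup_error")
  }
  label <- display_name(kb, concept$id)
  reasons <- reason_row(character(), character())[0, ]

  # hard exclusions first: non-negotiable regardless of MIND status
  if (concept$kind == "food") {
    if (excluded_by(kb, concept$id, patient$allergies)) {
      return(verdict("not_recommended", reason_row(
        guideline_provenance$allergy,
        sprintf("%s matches a declared allergy", label))))
    }
    if (excluded_by(kb, concept$id, patient$religious_constraints)) {
      return(verdict("not_recommended", reason_row(
        guideline_provenance$religious,
        sprintf("%s is excluded for religious reasons", label))))
    }
  }

  cls <- mind_classify(kb, concept$id)
  trace <- NULL
  if (concept$kind == "food") {
    target <- switch(cls, limit = "MindLimited", encourage = "MindEncouraged", NULL)
    if (!is.null(target)) {
      pr <- prove(atom(target, concept$id), kb = kb, rules = rules)
      if (pr$proven) trace <- pr$trace
    }
  }

  if (cls == "limit") {
    reasons <- reason_row(
      guideline_provenance$mind_limit,
      sprintf("%s is on the MIND diet's limit list", label))
  } else if (cls == "encourage") {
    reasons <- reason_row(
      guideline_provenance$mind_encourage,
      sprintf("%s is on the MIND diet's encouraged list", label))
  } else {
    reasons <- reason_row(
      guideline_provenance$mind_encourage,
      sprintf("%s is not specifically encouraged or limited by the MIND diet", label))
  }

  caution <- FALSE
  if (has_diabetes(patient) && concept$kind == "food") {
    sugar <- kb$foods[[concept$id]]$nutrients[["sugar_g"]]
    if (sugar >= 15) {
      caution <- TRUE
      reasons <- bind_rows(reasons, reason_row(
        guideline_provenance$ada_sugar,
        sprintf("%s is sugar-dense (%.0f g per 100 g) and the patient has diabetes",
                label, sugar)))
    }
  }

  suitable <- if (cls == "limit") "not_recommended"
  else if (cls == "encourage" && !caution) "recommended"
  else "caution"
  v <- verdict(suitable, reasons)
  v$trace <- trace
  v
}

display_name <- function(kb, id) {
  if (id %in% names(kb$foods)) return(kb$foods[[id]]$name)
  if (id %in% names(kb$classes)) return(kb$classes[[id]]$label)
  id
}

# foods typed (directly or via IS-A) as snack-suitable
snack_candidates <- function(kb) {
  keep(kb$foods, function(f) {
    anc <- concept_ancestry(kb, list(kind = "food", id = f$id))
    "snackfood" %in% norm_class_term(anc)
  })
}

#' Suggest a healthy snack
#'
#' Ranks the KB's snack-suitable foods by MIND class (encouraged, then
#' neutral, then limited), filters out the patient's exclusions and
#' anything already rejected this session, and returns the best
#' candidate (ties broken by lexicographic id, so the result is
#' deterministic).
#'
#' @param patient,caregiver Profiles.
#' @param kb The KB.
#' @param rules Guideline rules.
#' @param session Optional [dialogue_session()] whose rejected set is
#'   honored.
#' @return List with `food` (a [food_item()] or `NULL`) and `verdict`.
#' @export
suggest_snack <- function(patient, caregiver, kb,
                          rules = default_guideline_rules(), session = NULL) {
  cands <- snack_candidates(kb)
  if (length(cands) == 0L) {
    da_abort("knowledge base has no snack-class foods", "dietassist_lookup_error")
  }
  rejected <- if (!is.null(session)) session$rejected else character()
  cands <- keep(cands, function(f) {
    !f$id %in% rejected &&
      !excluded_by(kb, f$id, patient$allergies) &&
      !excluded_by(kb, f$id, patient$religious_constraints) &&
      !f$id %in% patient$dislikes
  })
  if (length(cands) == 0L) {
    return(list(food = NULL,
                verdict = verdict("caution", reason_row(
                  guideline_provenance$allergy,
                  "every snack candidate is excluded by the patient's profile"))))
  }
  rank <- map_int(cands, function(f) {
    switch(mind_classify(kb, f$id), encourage = 1L, neutral = 2L, limit = 3L)
  })
  ids <- map_chr(cands, "id")
  best <- ids[order(rank, ids)][1]
  list(food = kb$foods[[best]],
       verdict = check_food_suitability(best, "snack", patient, kb, rules))
}

count_encouraged_ingredients <- function(recipe, kb) {
  sum(map_lgl(unique(recipe$ingredients$food_id),
              ~ mind_classify(kb, .x) == "encourage"))
}

#' Recommend a recipe
#'
#' Candidates are the KB recipes matching the requested meal type, minus
#' recipes rejected earlier in the session, minus any with meal
#' constraint violations ([check_meal_constraints()]); optional
#' `servings` and `max_time` slots filter further. Candidates are
#' ranked by (1) number of MIND-encouraged ingredients, descending,
#' (2) distance of per-serving energy from the calorie-target midpoint,
#' ascending, (3) id, ascending. The rationale lists each satisfied
#' guideline with its provenance.
#'
#' @param slots Named list with at least `meal`; optional `servings`,
#'   `max_time`.
#' @param patient,caregiver Profiles.
#' @param kb The KB.
#' @param rules Guideline rules.
#' @param session Optional session (rejection memory).
#' @return List with `recipe` (or `NULL`), `rationale` (tibble of
#'   provenance + explanation), and on failure `reason` naming the
#'   binding constraint.
#' @export
recommend_recipe <- function(slots, patient, caregiver, kb,
                             rules = default_guideline_rules(), session = NULL) {
  meal <- slots$meal
  if (is.null(meal)) {
    da_abort("recipe recommendation needs at least the meal slot",
             "dietassist_validation_error")
  }
  meal <- match.arg(meal, meal_type_levels)
  rejected <- if (!is.null(session)) session$rejected else character()

  cands <- keep(kb$recipes, function(r) {
    meal %in% r$meal_types && !r$id %in% rejected &&
      (is.null(slots$servings) || r$servings >= slots$servings) &&
      (is.null(slots$max_time) || r$prep_time <= slots$max_time)
  })
  if (length(cands) == 0L) {
    return(list(recipe = NULL, rationale = NULL,
                reason = sprintf("no %s recipe matches the request", meal)))
  }
  admissible <- keep(cands, function(r) {
    nrow(check_meal_constraints(r, patient, caregiver, kb, meal = meal)) == 0L
  })
  if (length(admissible) == 0L) {
    # name the most common binding constraint across candidates
    vio <- bind_rows(map(cands, check_meal_constraints, patient = patient,
                         caregiver = caregiver, kb = kb, meal = meal))
    top <- names(sort(table(vio$constraint), decreasing = TRUE))[1]
    return(list(recipe = NULL, rationale = NULL,
                reason = sprintf("every %s candidate violates a constraint (most often: %s)",
                                 meal, top)))
  }

  target <- meal_calorie_target(patient, meal)
  mid <- mean(target)
  ids <- map_chr(admissible, "id")
  enc <- map_int(admissible, count_encouraged_ingredients, kb = kb)
  dist <- map_dbl(admissible, ~ abs(recipe_nutrients(.x, kb)[["energy_kcal"]] - mid))
  best <- admissible[[order(-enc, dist, ids)[1]]]

  nut <- recipe_nutrients(best, kb)
  rationale <- bind_rows(
    reason_row(attr(target, "provenance"),
               sprintf("per-serving energy %.0f kcal meets the %s target [%.0f, %.0f] kcal",
                       nut[["energy_kcal"]], meal, target[["lo"]], target[["hi"]])),
    if (has_diabetes(patient)) bind_rows(
      reason_row(guideline_provenance$ada_protein,
                 sprintf("protein supplies %.0f%% of meal energy (within 20-30%%)",
                         100 * 4 * nut[["protein_g"]] / nut[["energy_kcal"]])),
      reason_row(guideline_provenance$ada_sugar,
                 sprintf("sugar supplies %.0f%% of meal energy (below 10%%)",
                         100 * 4 * nut[["sugar_g"]] / nut[["energy_kcal"]]))
    ),
    reason_row(guideline_provenance$mind_encourage,
               sprintf("%d MIND-encouraged ingredient(s)",
                       count_encouraged_ingredients(best, kb))),
    reason_row(guideline_provenance$time,
               sprintf("ready in %.0f minutes (limit %.0f)",
                       best$prep_time, caregiver$time_limit)),
    reason_row(guideline_provenance$budget,
               sprintf("costs %.2f per serving (budget %.2f)",
                       best$cost / best$servings, caregiver$budget))
  )
  list(recipe = best, rationale = rationale, reason = NULL)
}

# ---- diet history -----------------------------------------------------------

#' Create a meal record
#'
#' @param date Calendar date (`Date` or `"YYYY-MM-DD"`).
#' @param meal Meal type.
#' @param items Character vector of recipe and/or food ids consumed.
#' @param kb The KB, used to derive the record's energy (per-serving
#'   energy for recipes, per-100 g energy for plain foods).
#' @return One-row tibble (`date`, `meal`, `items`, `energy_kcal`).
#' @export
meal_record <- function(date, meal, items, kb) {
  d <- tryCatch(as.Date(date), error = function(e) NA)
  if (is.na(d)) {
    da_abort(sprintf("malformed date '%s'", as.character(date)),
             "dietassist_validation_error")
  }
  meal <- match.arg(meal, meal_type_levels)
  energy <- sum(map_dbl(items, function(id) {
    if (id %in% names(kb$recipes)) {
      recipe_nutrients(kb$recipes[[id]], kb)[["energy_kcal"]]
    } else if (id %in% names(kb$foods)) {
      kb$foods[[id]]$nutrients[["energy_kcal"]]
    } else {
      da_abort(sprintf("meal record references unknown item '%s'", id),
               "dietassist_lookup_error")
    }
  }))
  tibble(date = d, meal = meal, items = paste(items, collapse = ";"),
         energy_kcal = energy)
}

#' Append a meal record to a history
#' @param history Tibble of meal records (may be zero rows or `NULL`).
#' @param record Output of [meal_record()].
#' @return The extended history tibble (append-only).
#' @export
record_meal <- function(history, record) {
  bind_rows(history, record)
}

#' Recall daily or weekly diet history
#'
#' @param history Meal-record tibble.
#' @param window `"day"` (that date's records) or `"week"` (the 7 days
#'   ending at `date`).
#' @param date Anchor date.
#' @return List with `records` (tibble) and `total_energy` (kcal).
#' @export
recall_history <- function(history, window = c("day", "week"), date) {
  window <- match.arg(window)
  d <- tryCatch(as.Date(date), error = function(e) NA)
  if (is.na(d)) {
    da_abort(sprintf("malformed date '%s'", as.character(date)),
             "dietassist_validation_error")
  }
  if (is.null(history) || nrow(history) == 0L) {
    return(list(records = meal_record("2000-01-01", "lunch", character(0),
                                      kb_new())[0, ],
                total_energy = 0))
  }
  from <- if (window == "day") d else d - 6
  sel <- history[history$date >= from & history$date <= d, , drop = FALSE]
  list(records = sel, total_energy = sum(sel$energy_kcal))
}

#' Write / read a meal history as JSONL
#' @param history Meal-record tibble.
#' @param path File path.
#' @export
write_meal_history <- function(history, path) {
  lines <- map_chr(seq_len(nrow(history)), function(i) {
    jsonlite::toJSON(list(date = as.character(history$date[i]),
                          meal = history$meal[i], items = history$items[i],
                          energy_kcal = history$energy_kcal[i]),
                     auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_meal_history
#' @export
read_meal_history <- function(path) {
  if (!file.exists(path)) return(NULL)
  lines <- readLines(path, warn = FALSE)
  bind_rows(map(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    tibble(date = as.Date(x$date), meal = x$meal, items = x$items,
           energy_kcal = x$energy_kcal)
  }))
}

# ---- tips -------------------------------------------------------------------

#' Load the tip bank
#' @param path YAML tip bank; defaults to the packaged one.
#' @return List of tips.
#' @export
load_tip_bank <- function(path = system.file("extdata", "tips.yaml",
                                             package = "dietassist")) {
  y <- yaml::read_yaml(path)
  if (length(y$tips) == 0L) {
    da_abort("tip bank is empty", "dietassist_validation_error")
  }
  y$tips
}

#' Get a caregiving tip
#'
#' Selects tips tagged with the requested category and ADRD stage
#' (falling back to stage-agnostic tips when none match the stage),
#' renders the requested education tier, and cycles deterministically
#' through the matching tips as `cursor` increases.
#'
#' @param tips Tip bank ([load_tip_bank()]).
#' @param category `"proper_diet"` or `"eating_challenge"`.
#' @param stage ADRD stage (`"early"`, `"middle"`, `"late"`).
#' @param tier Education tier.
#' @param cursor Non-negative integer; pass the session's running count
#'   of tips served to cycle through the bank.
#' @return List with `text` and `id`.
#' @export
get_tip <- function(tips, category, stage, tier = "standard", cursor = 0) {
  if (!category %in% c("proper_diet", "eating_challenge")) {
    da_abort(sprintf("unknown tip category '%s'", category),
             "dietassist_validation_error")
  }
  stage <- match.arg(stage, c("early", "middle", "late"))
  pool <- keep(tips, function(t) {
    t$category == category && (stage %in% unlist(t$stages))
  })
  if (length(pool) == 0L) {
    pool <- keep(tips, function(t) {
      t$category == category && ("any" %in% unlist(t$stages))
    })
  }
  if (length(pool) == 0L) {
    pool <- keep(tips, function(t) t$category == category)
  }
  if (length(pool) == 0L) {
    da_abort(sprintf("no tips available for category '%s'", category),
             "dietassist_validation_error")
  }
  pool <- pool[order(map_chr(pool, "id"))]
  t <- pool[[(cursor %% length(pool)) + 1L]]
  list(text = t$text[[tier]] %||% t$text[["standard"]], id = t$id)
}
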