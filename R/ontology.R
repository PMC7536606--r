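#' Ontology classes, individuals, and the knowledge base
#'
#' The knowledge base (KB) is a typed concept graph in the style of a
#' lightweight OWL ontology: named classes linked by IS-A (subclass)
#' edges, individuals asserted to belong to classes (the *type* relation),
#' plus the two domain-specific entity kinds the diet assistant needs --
#' food items carrying per-100 g nutrient records and recipes composed of
#' ingredient amounts. Classes and their axioms form the TBox; individuals
#' and their property assertions form the ABox.
#'
#' @name ontology
NULL

#' Create an ontology class
#'
#' @param name Class identifier (case-sensitive, unique within a KB).
#' @param label Human-readable display label; defaults to `name`.
#' @param parents Character vector of parent class identifiers (IS-A).
#' @param synonyms Character vector of surface synonyms (matched
#'   case-insensitively).
#' @param disjoint_with Character vector of class identifiers declared
#'   disjoint with this class.
#' @return An object of class `ont_class`.
#' @export
ont_class <- function(name, label = name, parents = character(),
                      synonyms = character(), disjoint_with = character()) {
  stopifnot(is_string(name), is_string(label))
  structure(
    list(name = name, label = label,
         parents = sort(unique(as.character(parents))),
         synonyms = sort(unique(as.character(synonyms))),
         disjoint_with = sort(unique(as.character(disjoint_with)))),
    class = "ont_class"
  )
}

#' Create an individual (ABox instance)
#'
#' @param id Individual identifier, unique within a KB.
#' @param types Character vector of class identifiers the individual
#'   belongs to.
#' @param properties A list of `(predicate, value)` assertions, given as a
#'   named list (`list(energy_kcal = 120)`); repeated predicates are
#'   allowed by passing a data frame with `predicate` and `value` columns.
#' @return An object of class `individual`.
#' @export
individual <- function(id, types = character(), properties = list()) {
  stopifnot(is_string(id))
  props <- as_property_table(properties)
  structure(
    list(id = id, types = sort(unique(as.character(types))), properties = props),
    class = "individual"
  )
}

as_property_table <- function(properties) {
  if (is.data.frame(properties)) {
    stopifnot(all(c("predicate", "value") %in% names(properties)))
    return(tibble(predicate = as.character(properties$predicate),
                  value = as.character(properties$value)))
  }
  if (length(properties) == 0L) {
    return(tibble(predicate = character(), value = character()))
  }
  stopifnot(!is.null(names(properties)), all(nzchar(names(properties))))
  tibble(
    predicate = rep(names(properties), lengths(properties)),
    value = as.character(unlist(properties, use.names = FALSE))
  )
}

nutrient_fields <- c("energy_kcal", "protein_g", "carb_g", "sugar_g",
                     "fat_g", "satfat_g", "fiber_g", "sodium_mg")

#' Create a food item
#'
#' Nutrients follow the FoodData Central convention: all values are per
#' 100 g edible portion.
#'
#' @param id Food identifier.
#' @param name Display name.
#' @param category Class identifier of the food's category (must exist in
#'   the KB the item is loaded into).
#' @param nutrients Named numeric vector/list with entries `energy_kcal`,
#'   `protein_g`, `carb_g`, `sugar_g`, `fat_g`, `satfat_g`, `fiber_g`,
#'   `sodium_mg`; all must be non-negative.
#' @param synonyms Character vector of alternative surface names.
#' @return An object of class `food_item`.
#' @export
food_item <- function(id, name, category, nutrients, synonyms = character()) {
  stopifnot(is_string(id), is_string(name), is_string(category))
  nut <- unlist(nutrients)[nutrient_fields]
  names(nut) <- nutrient_fields
  if (anyNA(nut)) {
    da_abort(sprintf("food '%s': missing nutrient field(s): %s", id,
                     paste(nutrient_fields[is.na(nut)], collapse = ", ")),
             "dietassist_format_error")
  }
  if (any(nut < 0)) {
    da_abort(sprintf("food '%s': negative nutrient value", id),
             "dietassist_format_error")
  }
  structure(
    list(id = id, name = name, category = category,
         nutrients = nut, synonyms = sort(unique(as.character(synonyms)))),
    class = "food_item"
  )
}

meal_type_levels <- c("breakfast", "lunch", "dinner", "snack")

#' Create a recipe
#'
#' @param id Recipe identifier.
#' @param name Display name.
#' @param ingredients Data frame with columns `food_id` (character) and
#'   `grams` (positive numeric), or a list of `list(food_id=, grams=)`.
#' @param servings Positive integer number of servings the recipe yields.
#' @param prep_time Preparation time in minutes.
#' @param cost Total cost of the prepared recipe, in currency units.
#' @param meal_types Subset of `"breakfast"`, `"lunch"`, `"dinner"`,
#'   `"snack"`.
#' @param cuisine_tags Character vector of cuisine tags.
#' @return An object of class `recipe`.
#' @export
recipe <- function(id, name, ingredients, servings, prep_time, cost,
                   meal_types, cuisine_tags = character()) {
  stopifnot(is_string(id), is_string(name))
  if (!is.data.frame(ingredients)) {
    ingredients <- tibble(
      food_id = map_chr(ingredients, ~ as.character(.x$food_id %||% .x[[1]])),
      grams = map_dbl(ingredients, ~ as.numeric(.x$grams %||% .x[[2]]))
    )
  }
  ingredients <- tibble(food_id = as.character(ingredients$food_id),
                        grams = as.numeric(ingredients$grams))
  if (!is_count(servings, min = 1)) {
    da_abort(sprintf("recipe '%s': servings must be a positive integer", id),
             "dietassist_format_error")
  }
  if (nrow(ingredients) == 0L || any(ingredients$grams <= 0)) {
    da_abort(sprintf("recipe '%s': every ingredient needs grams > 0", id),
             "dietassist_format_error")
  }
  meal_types <- as.character(meal_types)
  if (!all(meal_types %in% meal_type_levels)) {
    da_abort(sprintf("recipe '%s': unknown meal type(s): %s", id,
                     paste(setdiff(meal_types, meal_type_levels), collapse = ", ")),
             "dietassist_format_error")
  }
  structure(
    list(id = id, name = name, ingredients = ingredients,
         servings = as.integer(servings), prep_time = as.numeric(prep_time),
         cost = as.numeric(cost), meal_types = sort(unique(meal_types)),
         cuisine_tags = sort(unique(as.character(cuisine_tags)))),
    class = "recipe"
  )
}

#' @importFrom purrr map_dbl
NULL

#' Assemble and validate a knowledge base
#'
#' Validates all structural invariants: unique class names and individual
#' ids, no dangling IS-A parents or type references, an acyclic IS-A
#' graph (the cycle is named in the error), resolvable recipe
#' ingredients, and a collision-free synonym table.
#'
#' @param classes List of [ont_class()] objects.
#' @param individuals List of [individual()] objects.
#' @param foods List of [food_item()] objects.
#' @param recipes List of [recipe()] objects.
#' @return An object of class `diet_kb`.
#' @export
kb_new <- function(classes = list(), individuals = list(), foods = list(),
                   recipes = list()) {
  cls_names <- map_chr(classes, "name")
  if (anyDuplicated(cls_names)) {
    da_abort(sprintf("duplicate class name(s): %s",
                     paste(unique(cls_names[duplicated(cls_names)]), collapse = ", ")),
             "dietassist_integrity_error")
  }
  names(classes) <- cls_names

  # dangling parents / disjointness references
  for (cl in classes) {
    bad <- setdiff(c(cl$parents, cl$disjoint_with), cls_names)
    if (length(bad)) {
      da_abort(sprintf("class '%s' references undeclared class(es): %s",
                       cl$name, paste(bad, collapse = ", ")),
               "dietassist_integrity_error")
    }
  }
  check_isa_acyclic(classes)

  ind_ids <- map_chr(individuals, "id")
  if (anyDuplicated(ind_ids)) {
    da_abort(sprintf("duplicate individual id(s): %s",
                     paste(unique(ind_ids[duplicated(ind_ids)]), collapse = ", ")),
             "dietassist_integrity_error")
  }
  names(individuals) <- ind_ids
  for (ind in individuals) {
    bad <- setdiff(ind$types, cls_names)
    if (length(bad)) {
      da_abort(sprintf("individual '%s' has undeclared type(s): %s",
                       ind$id, paste(bad, collapse = ", ")),
               "dietassist_integrity_error")
    }
  }

  food_ids <- map_chr(foods, "id")
  if (anyDuplicated(food_ids)) {
    da_abort("duplicate food id(s)", "dietassist_integrity_error")
  }
  names(foods) <- food_ids
  for (f in foods) {
    if (!f$category %in% cls_names) {
      da_abort(sprintf("food '%s' has undeclared category '%s'", f$id, f$category),
               "dietassist_integrity_error")
    }
  }

  rec_ids <- map_chr(recipes, "id")
  if (anyDuplicated(rec_ids)) {
    da_abort("duplicate recipe id(s)", "dietassist_integrity_error")
  }
  names(recipes) <- rec_ids
  for (r in recipes) {
    bad <- setdiff(r$ingredients$food_id, food_ids)
    if (length(bad)) {
      da_abort(sprintf("recipe '%s' references unknown food id(s): %s",
                       r$id, paste(bad, collapse = ", ")),
               "dietassist_integrity_error")
    }
  }

  kb <- structure(
    list(classes = classes, individuals = individuals, foods = foods,
         recipes = recipes),
    class = "diet_kb"
  )
  check_synonym_collisions(kb)
  kb
}

# depth-first IS-A cycle check; errors with the offending cycle spelled out
check_isa_acyclic <- function(classes) {
  state <- new.env(parent = emptyenv()) # 1 = on stack, 2 = done
  visit <- function(name, path) {
    st <- state[[name]] %||% 0L
    if (st == 2L) return(invisible())
    if (st == 1L) {
      cyc <- c(path[which(path == name)[1]:length(path)], name)
      da_abort(sprintf("IS-A cycle detected: %s", paste(cyc, collapse = " -> ")),
               "dietassist_integrity_error")
    }
    state[[name]] <- 1L
    for (p in classes[[name]]$parents) visit(p, c(path, name))
    state[[name]] <- 2L
  }
  for (nm in names(classes)) visit(nm, character())
  invisible()
}

check_synonym_collisions <- function(kb) {
  entries <- synonym_entries(kb)
  if (nrow(entries) == 0L) return(invisible())
  by_term <- split(entries$concept, entries$term)
  clash <- names(by_term)[map_int(by_term, ~ length(unique(.x))) > 1L]
  if (length(clash)) {
    da_abort(sprintf("synonym collision(s): term(s) %s map to multiple concepts",
                     paste(sQuote(clash), collapse = ", ")),
             "dietassist_integrity_error")
  }
  invisible()
}

# all (surface term -> concept id) pairs declared anywhere in the KB
synonym_entries <- function(kb) {
  rows <- list()
  for (cl in kb$classes) {
    terms <- unique(norm_term(c(cl$label, cl$synonyms)))
    rows[[length(rows) + 1L]] <- tibble(term = terms, concept = cl$name)
  }
  for (f in kb$foods) {
    terms <- unique(norm_term(c(f$name, f$synonyms)))
    rows[[length(rows) + 1L]] <- tibble(term = terms, concept = f$id)
  }
  if (length(rows) == 0L) return(tibble(term = character(), concept = character()))
  distinct(bind_rows(rows))
}

#' @export
print.diet_kb <- function(x, ...) {
  cat(sprintf("<diet_kb> %d classes, %d individuals, %d foods, %d recipes\n",
              length(x$classes), length(x$individuals), length(x$foods),
              length(x$recipes)))
  invisible(x)
}

#' Transitive IS-A superclasses of a class
#'
#' Breadth-first transitive closure of the IS-A parent relation,
#' excluding the class itself; ties at equal depth are broken
#' lexicographically so the order is deterministic.
#'
#' @param kb A [kb_new()] knowledge base.
#' @param cls Class identifier.
#' @return Character vector of superclass identifiers, nearest first.
#' @export
superclasses <- function(kb, cls) {
  if (!cls %in% names(kb$classes)) {
    da_abort(sprintf("unknown class '%s'", cls), "dietassist_lookup_error")
  }
  out <- character()
  frontier <- cls
  while (length(frontier)) {
    parents <- sort(unique(unlist(map(frontier, ~ kb$classes[[.x]]$parents))))
    parents <- setdiff(parents, c(out, cls))
    out <- c(out, parents)
    frontier <- parents
  }
  out
}

# all classes subsumed by any of `tops` (including `tops` themselves)
descendant_classes <- function(kb, tops) {
  tops <- intersect(tops, names(kb$classes))
  out <- character()
  frontier <- tops
  children_of <- function(cls) {
    names(kb$classes)[map_lgl(kb$classes, ~ cls %in% .x$parents)]
  }
  while (length(frontier)) {
    out <- union(out, frontier)
    kids <- sort(unique(unlist(map(frontier, children_of))))
    frontier <- setdiff(kids, out)
  }
  sort(out)
}

#' Build the surface-term matching vocabulary
#'
#' Collects, for a set of top-level classes, every descendant class (via
#' IS-A), every individual and food item typed by those classes, and all
#' their labels and synonyms, into a case-insensitive map from surface
#' term to canonical concept identifier. The dialogue layer uses this map
#' to expand utterances with ontology concepts before intent matching.
#'
#' @param kb A knowledge base.
#' @param top_classes Character vector of top-level class identifiers.
#' @return Named character vector: names are normalized surface terms,
#'   values are concept identifiers, sorted by term.
#' @export
build_matching_vocabulary <- function(kb, top_classes) {
  bad <- setdiff(top_classes, names(kb$classes))
  if (length(bad)) {
    da_abort(sprintf("unknown top class(es): %s", paste(bad, collapse = ", ")),
             "dietassist_lookup_error")
  }
  if (length(top_classes) == 0L) return(stats::setNames(character(), character()))
  in_scope <- descendant_classes(kb, top_classes)

  rows <- list()
  for (cls in in_scope) {
    cl <- kb$classes[[cls]]
    terms <- unique(norm_term(c(cl$name, cl$label, cl$synonyms)))
    rows[[length(rows) + 1L]] <- tibble(term = terms, concept = cls)
  }
  covered <- function(types) length(intersect(types, in_scope)) > 0L
  for (ind in kb$individuals) {
    if (!covered(ind$types)) next
    rows[[length(rows) + 1L]] <- tibble(term = norm_term(ind$id), concept = ind$id)
  }
  for (f in kb$foods) {
    if (!covered(c(f$category, kb$individuals[[f$id]]$types))) next
    terms <- unique(norm_term(c(f$id, f$name, f$synonyms)))
    rows[[length(rows) + 1L]] <- tibble(term = terms, concept = f$id)
  }
  tab <- distinct(bind_rows(rows))
  # classes win over instance terms on the rare exact tie; then first-sorted
  tab <- tab[order(tab$term, !tab$concept %in% names(kb$classes), tab$concept), ]
  tab <- tab[!duplicated(tab$term), ]
  stats::setNames(tab$concept, tab$term)
}

#' Partition a knowledge base into TBox and ABox
#'
#' The TBox keeps terminological knowledge (class declarations with their
#' IS-A, synonym, and disjointness axioms); the ABox keeps assertional
#' knowledge (individuals with their types and properties, food items,
#' recipes). [merge_kb()] reassembles the original KB exactly.
#'
#' @param kb A knowledge base.
#' @return List with elements `tbox` and `abox`.
#' @export
partition_kb <- function(kb) {
  list(
    tbox = structure(list(classes = kb$classes), class = "diet_tbox"),
    abox = structure(list(individuals = kb$individuals, foods = kb$foods,
                          recipes = kb$recipes), class = "diet_abox")
  )
}

#' Merge a TBox and ABox back into a knowledge base
#'
#' @param tbox,abox The two halves produced by [partition_kb()].
#' @return A validated `diet_kb`; `merge_kb(partition_kb(kb))` round-trips
#'   losslessly.
#' @export
merge_kb <- function(tbox, abox) {
  kb_new(classes = unname(tbox$classes), individuals = unname(abox$individuals),
         foods = unname(abox$foods), recipes = unname(abox$recipes))
}
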