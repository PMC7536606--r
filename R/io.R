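#' Load a knowledge base from files
#'
#' Reads the three standard inputs and assembles a validated KB:
#'
#' * `food_table` -- CSV with header
#'   `id,name,category,energy_kcal,protein_g,carb_g,sugar_g,fat_g,satfat_g,fiber_g,sodium_mg`
#'   (nutrients per 100 g, FoodData Central style);
#' * `recipes` -- JSON, either a top-level array of recipe records or an
#'   object with a `recipes` array;
#' * `ontology` -- either the canonical JSON dialect
#'   (`{"classes": [...], "individuals": [...]}`) or a Turtle subset
#'   restricted to `rdfs:subClassOf`, `rdf:type`/`a`, `rdfs:label`, and
#'   `owl:disjointWith` triples.
#'
#' Every food item is additionally registered as an ABox individual typed
#' by its category (merged with any ontology-declared types for the same
#' id), with its nutrient values attached as numeric properties so
#' guideline rules can reason over them.
#'
#' @param food_table Path to the food composition CSV.
#' @param recipes Path to the recipe JSON file, or `NULL` for none.
#' @param ontology Path to the ontology file (JSON or Turtle).
#' @return A validated `diet_kb`.
#' @export
load_kb <- function(food_table, recipes = NULL, ontology) {
  for (p in compact(list(food_table, recipes, ontology))) {
    if (!file.exists(p)) {
      da_abort(sprintf("input file not found: %s", p), "dietassist_format_error")
    }
  }
  ont <- read_ontology(ontology)
  foods <- read_food_table(food_table)
  recs <- if (is.null(recipes)) list() else read_recipes(recipes)

  # mirror foods into the ABox, merging ontology-declared types/properties
  declared <- stats::setNames(ont$individuals, map_chr(ont$individuals, "id"))
  inds <- declared
  for (f in foods) {
    extra <- declared[[f$id]]
    props <- tibble(predicate = names(f$nutrients),
                    value = as.character(unname(f$nutrients)))
    if (!is.null(extra)) props <- distinct(bind_rows(extra$properties, props))
    inds[[f$id]] <- individual(
      id = f$id,
      types = union(f$category, extra$types %||% character()),
      properties = props
    )
  }
  kb_new(classes = ont$classes, individuals = unname(inds), foods = foods,
         recipes = recs)
}

#' Read a food composition table
#'
#' @param path CSV path (see [load_kb()] for the column contract).
#' @return List of [food_item()] objects.
#' @export
read_food_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("id", "name", "category", nutrient_fields)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    da_abort(sprintf("food table %s: missing column(s): %s", path,
                     paste(missing, collapse = ", ")),
             "dietassist_format_error")
  }
  foods <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    nut <- suppressWarnings(as.numeric(df[i, nutrient_fields]))
    if (anyNA(nut)) {
      bad <- nutrient_fields[is.na(nut)][1]
      da_abort(sprintf("food table %s line %d: non-numeric value in field '%s'",
                       path, i + 1L, bad), "dietassist_format_error")
    }
    syn <- if ("synonyms" %in% names(df) && nzchar(df$synonyms[i])) {
      trimws(strsplit(df$synonyms[i], ";", fixed = TRUE)[[1]])
    } else character()
    foods[[i]] <- food_item(df$id[i], df$name[i], df$category[i],
                            stats::setNames(nut, nutrient_fields), synonyms = syn)
  }
  foods
}

#' Write a food table CSV
#' @param foods List of [food_item()]s.
#' @param path Output path.
#' @export
write_food_table <- function(foods, path) {
  df <- bind_rows(map(foods, function(f) {
    c(list(id = f$id, name = f$name, category = f$category),
      as.list(f$nutrients),
      list(synonyms = paste(f$synonyms, collapse = ";")))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read recipes from JSON
#' @param path Recipe JSON path.
#' @return List of [recipe()] objects.
#' @export
read_recipes <- function(path) {
  x <- jsonlite::read_json(path)
  if (!is.null(x$recipes)) x <- x$recipes
  map(x, function(r) {
    tryCatch(
      recipe(id = r$id, name = r$name,
             ingredients = map(r$ingredients, ~ list(food_id = .x$food_id,
                                                     grams = .x$grams)),
             servings = r$servings, prep_time = r$prep_time, cost = r$cost,
             meal_types = unlist(r$meal_types),
             cuisine_tags = unlist(r$cuisine_tags %||% list())),
      error = function(e) {
        da_abort(sprintf("recipe file %s, record '%s': %s", path,
                         r$id %||% "?", conditionMessage(e)),
                 "dietassist_format_error")
      }
    )
  })
}

#' Write recipes to JSON
#' @param recipes List of [recipe()]s.
#' @param path Output path.
#' @export
write_recipes <- function(recipes, path) {
  out <- list(recipes = map(unname(recipes), function(r) {
    list(id = r$id, name = r$name,
         ingredients = map(seq_len(nrow(r$ingredients)), function(i) {
           list(food_id = r$ingredients$food_id[i], grams = r$ingredients$grams[i])
         }),
         servings = r$servings, prep_time = r$prep_time, cost = r$cost,
         meal_types = as.list(r$meal_types), cuisine_tags = as.list(r$cuisine_tags))
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read an ontology file (JSON dialect or Turtle subset)
#' @param path Ontology path; `.ttl` files are parsed as Turtle,
#'   everything else as JSON.
#' @return List with `classes` and `individuals`.
#' @export
read_ontology <- function(path) {
  if (grepl("\\.ttl$", path, ignore.case = TRUE)) {
    return(read_ontology_turtle(path))
  }
  x <- jsonlite::read_json(path)
  classes <- map(x$classes %||% list(), function(c) {
    ont_class(name = c$name, label = c$label %||% c$name,
              parents = unlist(c$parents %||% list()),
              synonyms = unlist(c$synonyms %||% list()),
              disjoint_with = unlist(c$disjoint_with %||% list()))
  })
  individuals <- map(x$individuals %||% list(), function(i) {
    props <- i$properties %||% list()
    if (length(props) && !is.null(props[[1]]$predicate)) {
      props <- tibble(predicate = map_chr(props, "predicate"),
                      value = map_chr(props, ~ as.character(.x$value)))
    }
    individual(id = i$id, types = unlist(i$types %||% list()), properties = props)
  })
  list(classes = classes, individuals = individuals)
}

#' Write an ontology to the canonical JSON dialect
#' @param classes List of [ont_class()]s.
#' @param individuals List of [individual()]s.
#' @param path Output path.
#' @export
write_ontology_json <- function(classes, individuals, path) {
  out <- list(
    classes = map(unname(classes), function(c) {
      list(name = c$name, label = c$label, parents = as.list(c$parents),
           synonyms = as.list(c$synonyms), disjoint_with = as.list(c$disjoint_with))
    }),
    individuals = map(unname(individuals), function(i) {
      list(id = i$id, types = as.list(i$types),
           properties = map(seq_len(nrow(i$properties)), function(k) {
             list(predicate = i$properties$predicate[k],
                  value = i$properties$value[k])
           }))
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

# Turtle subset: prefix declarations are skipped; recognised triples are
#   :A rdfs:subClassOf :B .   :i rdf:type :C .   :i a :C .
#   :A rdfs:label "..." .     :A owl:disjointWith :B .
read_ontology_turtle <- function(path) {
  lines <- readLines(path, warn = FALSE)
  strip <- function(x) sub("^.*[:#/]", "", x)
  classes <- new.env(parent = emptyenv())
  ind_types <- list()
  ensure <- function(name) {
    if (is.null(classes[[name]])) {
      classes[[name]] <- list(name = name, label = name, parents = character(),
                              synonyms = character(), disjoint = character())
    }
  }
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(ln) || grepl("^@prefix", ln)) next
    m <- regmatches(ln, regexec(
      "^(\\S+)\\s+(rdfs:subClassOf|rdf:type|a|rdfs:label|owl:disjointWith)\\s+(.+?)\\s*\\.$", ln))[[1]]
    if (length(m) != 4L) {
      da_abort(sprintf("turtle parse error at %s line %d: %s", path, i, ln),
               "dietassist_format_error")
    }
    s <- strip(m[2]); pred <- m[3]; o <- m[4]
    if (pred == "rdfs:subClassOf") {
      o <- strip(o); ensure(s); ensure(o)
      classes[[s]]$parents <- union(classes[[s]]$parents, o)
    } else if (pred %in% c("rdf:type", "a")) {
      o <- strip(o); ensure(o)
      ind_types[[s]] <- union(ind_types[[s]], o)
    } else if (pred == "rdfs:label") {
      lab <- gsub('^"|"$', "", o); ensure(s)
      classes[[s]]$label <- lab
    } else if (pred == "owl:disjointWith") {
      o <- strip(o); ensure(s); ensure(o)
      classes[[s]]$disjoint <- union(classes[[s]]$disjoint, o)
    }
  }
  list(
    classes = map(as.list(classes), function(c) {
      ont_class(c$name, label = c$label, parents = c$parents,
                disjoint_with = c$disjoint)
    }),
    individuals = map(names(ind_types), function(id) {
      individual(id, types = ind_types[[id]])
    })
  )
}

#' Read patient and caregiver profiles from JSON
#'
#' Expects `{"patients": [...], "caregivers": [...]}`; each patient
#' record follows [patient_profile()] and each caregiver record
#' [caregiver_profile()].
#'
#' @param path Profile JSON path.
#' @return List with named lists `patients` and `caregivers`.
#' @export
read_profiles <- function(path) {
  x <- jsonlite::read_json(path)
  pats <- map(x$patients %||% list(), function(p) {
    patient_profile(
      id = p$id, age = p$age, sex = p$sex, adrd_stage = p$adrd_stage,
      comorbidities = unlist(p$comorbidities %||% list()),
      allergies = unlist(p$allergies %||% list()),
      dislikes = unlist(p$dislikes %||% list()),
      preferences = unlist(p$preferences %||% list()),
      religious_constraints = unlist(p$religious_constraints %||% list()),
      eer = p$eer, meals_per_day = p$meals_per_day %||% 3,
      weight_kg = p$weight_kg, height_m = p$height_m
    )
  })
  cgs <- map(x$caregivers %||% list(), function(c) {
    caregiver_profile(id = c$id, time_limit = c$time_limit, budget = c$budget,
                      education_level = c$education_level)
  })
  list(patients = stats::setNames(pats, map_chr(pats, "id")),
       caregivers = stats::setNames(cgs, map_chr(cgs, "id")))
}

#' Write profiles to JSON
#' @param patients,caregivers Lists of profile objects.
#' @param path Output path.
#' @export
write_profiles <- function(patients, caregivers, path) {
  drop_null <- function(x) x[!map_lgl(x, is.null)]
  out <- list(
    patients = map(unname(patients), ~ drop_null(unclass(.x))),
    caregivers = map(unname(caregivers), ~ drop_null(unclass(.x)))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
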