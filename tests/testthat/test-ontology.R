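test_that("superclasses computes the transitive IS-A closure", {
  kb <- toy_dairy_kb()
  expect_equal(superclasses(kb, "Cheese"), c("Dairy", "Food"))
  expect_equal(superclasses(kb, "Food"), character())
  expect_error(superclasses(kb, "Nope"), class = "dietassist_lookup_error")

  # diamond: X IS-A A, X IS-A B, A IS-A R, B IS-A R -> {A, B, R}, R once
  kbd <- kb_new(classes = list(
    ont_class("R"), ont_class("A", parents = "R"), ont_class("B", parents = "R"),
    ont_class("X", parents = c("A", "B"))
  ))
  expect_equal(superclasses(kbd, "X"), c("A", "B", "R"))
})

test_that("IS-A cycles are rejected at load with the cycle named", {
  err <- expect_error(
    kb_new(classes = list(
      ont_class("A", parents = "B"), ont_class("B", parents = "C"),
      ont_class("C", parents = "A")
    )),
    class = "dietassist_integrity_error"
  )
  expect_match(conditionMessage(err), "cycle")
  expect_match(conditionMessage(err), "A")
})

test_that("structural integrity errors name the offending reference", {
  expect_error(kb_new(classes = list(ont_class("A", parents = "Ghost"))),
               "Ghost", class = "dietassist_integrity_error")
  expect_error(
    kb_new(classes = list(ont_class("Food")),
           individuals = list(individual("i1", types = "Ghost"))),
    "Ghost", class = "dietassist_integrity_error")
  expect_error(
    kb_new(classes = list(ont_class("Food")),
           foods = list(food_item("f1", "f1", "Food",
                                  stats::setNames(rep(1, 8),
                                                  dietassist:::nutrient_fields))),
           recipes = list(recipe("r1", "r1",
                                 data.frame(food_id = "ghost_food", grams = 10),
                                 servings = 1L, prep_time = 5, cost = 1,
                                 meal_types = "lunch"))),
    "ghost_food", class = "dietassist_integrity_error")
})

test_that("food and recipe invariants are enforced", {
  nut <- stats::setNames(rep(1, 8), dietassist:::nutrient_fields)
  bad <- nut; bad["sugar_g"] <- -1
  expect_error(food_item("f", "f", "Food", bad),
               class = "dietassist_format_error")
  expect_error(recipe("r", "r", data.frame(food_id = "f", grams = 0),
                      servings = 1L, prep_time = 5, cost = 1,
                      meal_types = "lunch"),
               class = "dietassist_format_error")
  expect_error(recipe("r", "r", data.frame(food_id = "f", grams = 10),
                      servings = 0, prep_time = 5, cost = 1,
                      meal_types = "lunch"),
               class = "dietassist_format_error")
})

test_that("matching vocabulary covers descendants, instances, and synonyms", {
  kb <- kb_new(
    classes = list(
      ont_class("Food", label = "food"),
      ont_class("Dairy", label = "dairy", parents = "Food"),
      ont_class("Unrelated")
    ),
    individuals = list(individual("cheese_wheel", types = "Dairy")),
    foods = list(food_item("cheddar_cheese", "cheddar cheese", "Dairy",
                           stats::setNames(rep(1, 8),
                                           dietassist:::nutrient_fields),
                           synonyms = "cheddar"))
  )
  v <- build_matching_vocabulary(kb, "Food")
  expect_equal(unname(v["cheese_wheel"]), "cheese_wheel")
  expect_equal(unname(v["cheddar"]), "cheddar_cheese")
  expect_equal(unname(v["dairy"]), "Dairy")
  expect_false("unrelated" %in% names(v))
  expect_length(build_matching_vocabulary(kb, character()), 0L)
  expect_error(build_matching_vocabulary(kb, "Ghost"),
               class = "dietassist_lookup_error")

  # monotone in top_classes: adding a top never removes a term
  v2 <- build_matching_vocabulary(kb, c("Food", "Unrelated"))
  expect_true(all(names(v) %in% names(v2)))
})

test_that("synonym collisions are rejected at load", {
  nut <- stats::setNames(rep(1, 8), dietassist:::nutrient_fields)
  expect_error(
    kb_new(classes = list(ont_class("Food"),
                          ont_class("Snacks", parents = "Food",
                                    synonyms = "nibbles")),
           foods = list(food_item("f1", "nibbles", "Food", nut))),
    "nibbles", class = "dietassist_integrity_error")
})

test_that("partition_kb separates TBox and ABox losslessly", {
  nut <- stats::setNames(rep(1, 8), dietassist:::nutrient_fields)
  classes <- lapply(1:10, function(i) {
    ont_class(paste0("C", i), parents = if (i > 1) paste0("C", i - 1) else character())
  })
  inds <- lapply(1:30, function(i) {
    individual(paste0("i", i), types = paste0("C", (i %% 10) + 1),
               properties = list(score = i))
  })
  kb <- kb_new(classes = classes, individuals = inds)
  parts <- partition_kb(kb)
  expect_length(parts$tbox$classes, 10L)
  expect_length(parts$abox$individuals, 30L)
  expect_length(parts$abox$foods, 0L)
  merged <- merge_kb(parts$tbox, parts$abox)
  expect_equal(merged, kb)

  # no individuals -> empty ABox
  kb0 <- kb_new(classes = classes)
  expect_length(partition_kb(kb0)$abox$individuals, 0L)
})

test_that("load_kb reads the generated bundle and validates it", {
  dir <- fixture_dir()
  kb <- load_kb(file.path(dir, "foods.csv"), file.path(dir, "recipes.json"),
                file.path(dir, "ontology.json"))
  expect_length(kb$foods, 50L)
  expect_length(kb$recipes, 20L)
  for (f in kb$foods) {
    expect_true(all(f$nutrients >= 0))
    expect_true(f$category %in% names(kb$classes))
  }

  # header-only food table -> valid empty KB
  empty_csv <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,name,category,energy_kcal,protein_g,carb_g,sugar_g,fat_g,satfat_g,fiber_g,sodium_mg",
             empty_csv)
  kb0 <- load_kb(empty_csv, NULL, file.path(dir, "ontology.json"))
  expect_length(kb0$foods, 0L)

  # recipe referencing an unknown food id -> integrity error naming it
  bad_json <- withr::local_tempfile(fileext = ".json")
  writeLines('{"recipes":[{"id":"rX","name":"bad","ingredients":[{"food_id":"no_such_food","grams":50}],"servings":1,"prep_time":5,"cost":1,"meal_types":["lunch"]}]}',
             bad_json)
  expect_error(load_kb(file.path(dir, "foods.csv"), bad_json,
                       file.path(dir, "ontology.json")),
               "no_such_food", class = "dietassist_integrity_error")
})

test_that("the Turtle subset reader parses subclass/type/label triples", {
  ttl <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix : <http://example.org/> .",
    "# food hierarchy",
    ":Cheese rdfs:subClassOf :Dairy .",
    ":Dairy rdfs:subClassOf :Food .",
    ':Cheese rdfs:label "cheese" .',
    ":gouda rdf:type :Cheese .",
    ":VegMeal owl:disjointWith :MeatMeal ."
  ), ttl)
  ont <- read_ontology(ttl)
  nms <- vapply(ont$classes, function(c) c$name, character(1))
  expect_true(all(c("Cheese", "Dairy", "Food", "VegMeal", "MeatMeal") %in% nms))
  cheese <- ont$classes[[which(nms == "Cheese")]]
  expect_equal(cheese$parents, "Dairy")
  expect_equal(cheese$label, "cheese")
  expect_equal(ont$individuals[[1]]$id, "gouda")

  bad <- withr::local_tempfile(fileext = ".ttl")
  writeLines(":A weird :B .", bad)
  err <- expect_error(read_ontology(bad), class = "dietassist_format_error")
  expect_match(conditionMessage(err), "line 1")
})
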