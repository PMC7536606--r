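# Independent naive forward-chaining fixpoint oracle for positive
# function-free Datalog, by brute-force enumeration of substitutions.
# Deliberately shares no code with the package's tabled evaluator.

atom_str <- function(pred, args) paste0(pred, "(", paste(args, collapse = ","), ")")

fc_oracle <- function(rules, facts) {
  db <- new.env(parent = emptyenv())
  add <- function(pred, args) {
    key <- atom_str(pred, args)
    if (is.null(db[[key]])) {
      db[[key]] <- list(pred = pred, args = args)
      TRUE
    } else FALSE
  }
  for (f in facts) add(f$pred, f$args)
  consts <- unique(unlist(c(
    lapply(facts, function(f) f$args),
    lapply(rules, function(r) {
      unlist(lapply(c(r$body, list(r$head)),
                    function(a) a$args[!startsWith(a$args, "?")]))
    })
  )))
  holds <- function(pred, args) !is.null(db[[atom_str(pred, args)]])
  repeat {
    changed <- FALSE
    for (r in rules) {
      vars <- unique(unlist(lapply(c(r$body, list(r$head)), function(a) {
        a$args[startsWith(a$args, "?")]
      })))
      combos <- if (length(vars) == 0L) list(character()) else {
        grid <- do.call(expand.grid,
                        c(rep(list(consts), length(vars)),
                          stringsAsFactors = FALSE))
        lapply(seq_len(nrow(grid)), function(i) {
          stats::setNames(as.character(grid[i, ]), vars)
        })
      }
      for (sub in combos) {
        inst <- function(a) {
          vapply(a$args, function(t) {
            if (startsWith(t, "?")) unname(sub[t]) else t
          }, character(1))
        }
        ok <- all(vapply(r$body, function(a) holds(a$pred, inst(a)), logical(1)))
        if (ok && add(r$head$pred, inst(r$head))) changed <- TRUE
      }
    }
    if (!changed) break
  }
  # sorted character vector of ground atoms
  sort(ls(db))
}

# engine-side ground-atom listing for the same program, via query()
engine_atoms <- function(rules, facts) {
  preds <- unique(c(
    vapply(facts, function(f) f$pred, character(1)),
    unlist(lapply(rules, function(r) {
      vapply(c(r$body, list(r$head)), function(a) a$pred, character(1))
    }))
  ))
  arity <- function(p) {
    for (f in facts) if (f$pred == p) return(length(f$args))
    for (r in rules) {
      for (a in c(r$body, list(r$head))) {
        if (a$pred == p) return(length(a$args))
      }
    }
    1L
  }
  out <- character()
  for (p in sort(preds)) {
    vars <- paste0("?v", seq_len(arity(p)))
    ans <- query(list(atom(p, vars)), rules = rules, facts = facts)
    if (nrow(ans) == 0L) next
    for (i in seq_len(nrow(ans))) {
      out <- c(out, atom_str(p, as.character(unlist(ans[i, ]))))
    }
  }
  sort(out)
}

# random safe positive Datalog program
random_program <- function(n_preds = 5, n_rules = 6, n_consts = 5,
                           n_facts = 6) {
  preds <- paste0("P", seq_len(n_preds))
  arities <- sample(1:2, n_preds, replace = TRUE)
  names(arities) <- preds
  consts <- paste0("c", seq_len(n_consts))
  vars <- c("?x", "?y", "?z")
  rand_atom <- function(allowed_terms) {
    p <- sample(preds, 1)
    atom(p, sample(allowed_terms, arities[[p]], replace = TRUE))
  }
  rules <- list()
  for (i in seq_len(n_rules)) {
    nb <- sample(1:3, 1)
    body <- lapply(seq_len(nb), function(j) rand_atom(c(vars, consts)))
    bvars <- unique(unlist(lapply(body, function(a) a$args[startsWith(a$args, "?")])))
    head_terms <- if (length(bvars)) c(bvars, consts) else consts
    hp <- sample(preds, 1)
    head <- atom(hp, sample(head_terms, arities[[hp]], replace = TRUE))
    rules[[i]] <- horn_rule(sprintf("g%d", i), body, head)
  }
  facts <- lapply(seq_len(n_facts), function(i) rand_atom(consts))
  list(rules = rules, facts = facts)
}

# extra ground facts drawn over a program's own predicates/arities
random_extra_facts <- function(prog, n = 2, consts = paste0("c", 1:6)) {
  sigs <- unique(do.call(rbind, lapply(c(
    prog$facts,
    unlist(lapply(prog$rules, function(r) c(r$body, list(r$head))),
           recursive = FALSE)
  ), function(a) data.frame(pred = a$pred, k = length(a$args)))))
  lapply(seq_len(n), function(i) {
    s <- sigs[sample(nrow(sigs), 1), ]
    atom(s$pred, sample(consts, s$k, replace = TRUE))
  })
}

# ---- small hand-built knowledge bases ---------------------------------------

toy_dairy_kb <- function() {
  kb_new(
    classes = list(
      ont_class("Food"),
      ont_class("Dairy", parents = "Food"),
      ont_class("Cheese", parents = "Dairy")
    ),
    individuals = list(individual("gouda", types = "Cheese"))
  )
}

# single-food KB whose one recipe hits the diabetic dinner band exactly:
# per serving 510 kcal, protein 25% of energy, sugar 6% of energy
compliant_dinner_kb <- function() {
  protein <- 0.25 * 510 / 4   # 31.875 g
  sugar <- 0.06 * 510 / 4     # 7.65 g
  carb <- 40
  fat <- (510 - 4 * protein - 4 * carb) / 9
  kb_new(
    classes = list(ont_class("Food"), ont_class("Fish", parents = "Food")),
    foods = list(food_item(
      "plated_dinner", "plated dinner", "Fish",
      c(energy_kcal = 510, protein_g = protein, carb_g = carb,
        sugar_g = sugar, fat_g = fat, satfat_g = 2, fiber_g = 3,
        sodium_mg = 300))),
    recipes = list(recipe(
      "rx", "compliant dinner",
      data.frame(food_id = "plated_dinner", grams = 100),
      servings = 1L, prep_time = 25, cost = 5, meal_types = "dinner"))
  )
}

diabetic_patient <- function(...) {
  patient_profile(age = 65, sex = "male", adrd_stage = "early",
                  comorbidities = "type2_diabetes", eer = 2000,
                  meals_per_day = 3, ...)
}

# shared fixture bundle, generated once per test run
fixture_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "dietassist-fixtures")
      if (!file.exists(file.path(dir, "manifest.json"))) {
        generate_fixture_bundle(fixture_spec(seed = 1), dir)
      }
    }
    dir
  }
})

fixture_app <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- load_fixture_app(fixture_dir())
    fx
  }
})
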