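test_that("backward chaining proves the two-rule subsumption scenario", {
  rules <- parse_rules(text = c(
    "r1: A(?y) ^ D(?y) -> C(?y)",
    "r2: C(?y) -> B(?y)"
  ))
  facts <- list(atom("A", "x"), atom("D", "x"))
  pr <- prove(atom("B", "x"), rules = rules, facts = facts)
  expect_true(pr$proven)
  expect_equal(nrow(pr$trace), 2L) # two rule applications: r2 then r1
  expect_equal(pr$trace$rule, c("r2", "r1"))

  # a directly asserted fact needs no rule expansion
  pr2 <- prove(atom("B", "x"), facts = list(atom("B", "x")))
  expect_true(pr2$proven)
  expect_equal(nrow(pr2$trace), 0L)

  # a goal mentioned in no fact or head is not proven
  expect_false(prove(atom("E", "x"), rules = rules, facts = facts)$proven)
})

test_that("conjunctive queries enumerate all substitutions deterministically", {
  kb <- fixture_app()$kb
  rules <- fixture_app()$app$rules

  # every food is entailed to be a Food through IS-A subsumption rules
  ans <- query(list(atom("Food", "?f")), kb = kb)
  expect_equal(nrow(ans), 50L)
  expect_equal(ans$f, sort(ans$f))

  # two-atom conjunction: snack-typed and MIND-encouraged
  good <- query(list(atom("SnackFood", "?f"), atom("MindEncouraged", "?f")),
                kb = kb, rules = rules)
  brute <- sort(names(purrr::keep(kb$foods, function(fd) {
    anc <- c(fd$category, kb$individuals[[fd$id]]$types)
    "SnackFood" %in% anc && mind_classify(kb, fd$id) == "encourage"
  })))
  expect_equal(good$f, brute)
  expect_gt(nrow(good), 0L)

  # contradictory comparisons are unsatisfiable
  empty <- query(list(atom("Food", "?v"), atom("lt", c("?v", "1")),
                      atom("gt", c("?v", "2"))), kb = kb)
  expect_equal(nrow(empty), 0L)

  # determinism
  expect_identical(query(list(atom("Food", "?f")), kb = kb), ans)
})

test_that("numeric built-ins filter and bind over property values", {
  facts <- list(atom("sugar_g", c("choc", "55")), atom("sugar_g", c("kale", "1")))
  high <- query(list(atom("sugar_g", c("?f", "?s")), atom("gt", c("?s", "20"))),
                facts = facts)
  expect_equal(high$f, "choc")
  dbl <- query(list(atom("sugar_g", c("choc", "?s")),
                    atom("mul", c("?s", "2", "?d"))), facts = facts)
  expect_equal(dbl$d, "110")
  expect_error(
    query(list(atom("gt", c("?a", "1"))), facts = facts),
    class = "dietassist_validation_error") # unsafe: ?a never bound
})

test_that("rule safety and arity are validated", {
  expect_error(horn_rule("u", list(atom("A", "?x")), atom("B", "?y")),
               class = "dietassist_validation_error")
  expect_error(
    horn_rule("u2", list(atom("A", "?x"), atom("B", "?y", neg = TRUE)),
              atom("C", "?x")),
    class = "dietassist_validation_error")
  expect_error(
    prove(atom("P", "a"),
          rules = parse_rules(text = "r: P(?x, ?y) -> Q(?x)"),
          facts = list(atom("P", "b"))),
    class = "dietassist_validation_error")
})

test_that("stratified negation works and negative recursion is rejected", {
  rules <- parse_rules(text = "n1: A(?x) ^ not B(?x) -> C(?x)")
  ans <- query(atom("C", "?x"), rules = rules,
               facts = list(atom("A", "a"), atom("A", "b"), atom("B", "b")))
  expect_equal(ans$x, "a")
  bad <- parse_rules(text = c("p1: A(?x) ^ not Q(?x) -> P(?x)",
                              "p2: A(?x) ^ not P(?x) -> Q(?x)"))
  expect_error(query(atom("P", "?x"), rules = bad,
                     facts = list(atom("A", "a"))),
               class = "dietassist_validation_error")
})

test_that("cyclic rule graphs terminate via memoized answer tables", {
  rules <- parse_rules(text = c(
    "t1: edge(?x, ?y) -> path(?x, ?y)",
    "t2: edge(?x, ?y) ^ path(?y, ?z) -> path(?x, ?z)",
    "loop: path(?x, ?y) -> path(?x, ?y)" # direct self-recursion
  ))
  facts <- list(atom("edge", c("a", "b")), atom("edge", c("b", "c")),
                atom("edge", c("c", "a")))
  ans <- query(list(atom("path", c("?x", "?y"))), rules = rules, facts = facts)
  expect_equal(nrow(ans), 9L) # full closure of the 3-cycle
  expect_true(prove(atom("path", c("a", "a")), rules = rules,
                    facts = facts)$proven)
})

test_that("prover and query agree with the forward-chaining oracle", {
  set.seed(42)
  for (i in 1:120) {
    prog <- random_program(n_preds = sample(2:5, 1),
                           n_rules = sample(2:6, 1),
                           n_consts = sample(2:5, 1),
                           n_facts = sample(2:8, 1))
    expected <- fc_oracle(prog$rules, prog$facts)
    got <- engine_atoms(prog$rules, prog$facts)
    expect_identical(got, expected)
  }
})

test_that("entailment is monotone in the fact base", {
  set.seed(7)
  for (i in 1:30) {
    prog <- random_program()
    before <- engine_atoms(prog$rules, prog$facts)
    extra <- random_extra_facts(prog, n = 2)
    after <- engine_atoms(prog$rules, c(prog$facts, extra))
    expect_true(all(before %in% after))
  }
})

test_that("proof traces replay: every traced subgoal is entailed", {
  set.seed(11)
  for (i in 1:20) {
    prog <- random_program()
    entailed <- fc_oracle(prog$rules, prog$facts)
    if (length(entailed) == 0L) next
    # prove the lexicographically last entailed atom (most likely derived)
    g <- entailed[length(entailed)]
    m <- regmatches(g, regexec("^([^(]+)\\((.*)\\)$", g))[[1]]
    goal <- atom(m[2], strsplit(m[3], ",", fixed = TRUE)[[1]])
    pr <- prove(goal, rules = prog$rules, facts = prog$facts)
    expect_true(pr$proven)
    if (nrow(pr$trace)) {
      sub_atoms <- gsub("\\s", "", gsub("^not ", "", pr$trace$subgoal))
      expect_true(all(sub_atoms %in% entailed))
      expect_equal(sub_atoms[1], g) # trace starts at the goal
    }
  }
})

test_that("is_subsumed follows the IS-A closure reflexively", {
  kb <- toy_dairy_kb()
  expect_true(is_subsumed(kb, "Cheese", "Food"))
  expect_true(is_subsumed(kb, "Cheese", "Cheese"))
  expect_false(is_subsumed(kb, "Food", "Cheese"))
  expect_error(is_subsumed(kb, "Cheese", "Nope"),
               class = "dietassist_lookup_error")
})

test_that("satisfiability check reports entailed disjointness conflicts", {
  kb <- kb_new(
    classes = list(
      ont_class("Meal"),
      ont_class("VegetarianMeal", parents = "Meal",
                disjoint_with = "ContainsMeat"),
      ont_class("ContainsMeat", parents = "Meal"),
      ont_class("Meat")
    ),
    individuals = list(
      individual("stew", types = "VegetarianMeal",
                 properties = list(hasIngredient = "beef")),
      individual("beef", types = "Meat")
    )
  )
  rules <- parse_rules(text =
    "m1: hasIngredient(?m, ?i) ^ Meat(?i) -> ContainsMeat(?m)")
  conflicts <- check_satisfiability(kb, rules)
  expect_length(conflicts, 1L)
  expect_equal(conflicts[[1]]$individual, "stew")
  expect_setequal(conflicts[[1]]$classes, c("VegetarianMeal", "ContainsMeat"))
  expect_true("m1" %in% conflicts[[1]]$trace$rule)

  # no disjointness axioms -> trivially satisfiable
  expect_length(check_satisfiability(toy_dairy_kb()), 0L)

  # the shipped fixture bundle is conflict-free
  fx <- fixture_app()
  expect_length(check_satisfiability(fx$kb, fx$app$rules), 0L)
})

test_that("rule parsing round-trips text and JSON with provenance", {
  txt <- c("# comment",
           'mind.x: Vegetables(?f) -> MindEncouraged(?f) @ "MIND citation"',
           "plain(?a) ^ le(?a, 5) -> small(?a)")
  rules <- parse_rules(text = txt)
  expect_length(rules, 2L)
  expect_equal(rules[[1]]$id, "mind.x")
  expect_equal(rules[[1]]$provenance, "MIND citation")
  expect_equal(rules[[2]]$body[[2]]$pred, "le")

  jf <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(list(
    id = "j1", provenance = "cite",
    body = list(list(pred = "A", args = list("?x")),
                list(pred = "B", args = list("?x"), neg = TRUE)),
    head = list(pred = "C", args = list("?x"))
  )), auto_unbox = TRUE), jf)
  jr <- parse_rules_json(jf)
  expect_length(jr, 1L)
  expect_true(jr[[1]]$body[[2]]$neg)

  err <- expect_error(parse_rules(text = "A(?x) B(?x)"),
                      class = "dietassist_format_error")
  expect_match(conditionMessage(err), "line 1")
})
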