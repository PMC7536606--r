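#' Goal-driven inference over the knowledge base
#'
#' The reasoner answers goals by backward chaining: starting from the
#' goal predicate it collects exactly the predicates reachable through
#' rule bodies (so no unrelated part of the KB is ever touched),
#' stratifies them with respect to negation, and saturates each stratum
#' with a tabled fixpoint. The answer tables memoize repeated goals, so
#' cyclic rule graphs terminate, and every derived fact keeps the rule
#' and ground subgoals that first produced it, which is how proof traces
#' are reconstructed. For function-free safe Horn programs this tabled
#' procedure computes the same least fixpoint as naive forward chaining.
#'
#' Facts are drawn from the KB's ABox: for every individual, a unary
#' class-membership fact per asserted type, and a binary fact per
#' property assertion. IS-A subsumption is compiled into rules
#' (`Sub(?x) -> Super(?x)`), so entailed memberships carry traces too.
#'
#' @name inference
NULL

# ---- engine construction ----------------------------------------------------

tuple_key <- function(m) {
  if (nrow(m) == 0L) return(character())
  apply(m, 1L, paste, collapse = "\x1f")
}

empty_rel <- function(arity) matrix(character(), ncol = arity, nrow = 0L)

# bindings representation: a character data frame, one column per bound
# variable; TRUE is the 1-row/0-column frame, FALSE any 0-row frame
true_bindings <- function() as.data.frame(matrix(nrow = 1L, ncol = 0L))

# base facts: list pred -> character matrix (one row per tuple)
base_facts <- function(kb, facts) {
  out <- list()
  add <- function(pred, row) {
    out[[pred]] <<- rbind(out[[pred]], row)
  }
  if (!is.null(kb)) {
    for (ind in kb$individuals) {
      for (ty in ind$types) add(ty, ind$id)
      if (nrow(ind$properties)) {
        for (k in seq_len(nrow(ind$properties))) {
          add(ind$properties$predicate[k],
              c(ind$id, ind$properties$value[k]))
        }
      }
    }
  }
  for (f in facts) {
    if (any(map_lgl(f$args, is_var))) {
      da_abort(sprintf("fact %s must be ground", format(f)),
               "dietassist_validation_error")
    }
    add(f$pred, f$args)
  }
  map(out, function(m) {
    dimnames(m) <- NULL
    unique(m)
  })
}

# IS-A edges as subsumption rules so class membership propagates upward
isa_rules <- function(kb) {
  if (is.null(kb)) return(list())
  out <- list()
  for (cl in kb$classes) {
    for (p in cl$parents) {
      out[[length(out) + 1L]] <- horn_rule(
        id = sprintf("isa.%s.%s", cl$name, p),
        body = list(atom(cl$name, "?x")),
        head = atom(p, "?x"),
        provenance = "ontology IS-A axiom"
      )
    }
  }
  out
}

new_engine <- function(kb = NULL, rules = list(), facts = list()) {
  rules <- c(rules, isa_rules(kb))
  ids <- map_chr(rules, "id")
  if (anyDuplicated(ids)) {
    da_abort(sprintf("duplicate rule id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "dietassist_validation_error")
  }
  env <- new.env(parent = emptyenv())
  env$base <- base_facts(kb, facts)
  env$rules <- rules
  env$rules_by_head <- split(rules, map_chr(rules, ~ .x$head$pred))
  env$table <- list()    # pred -> matrix of derived tuples (incl. base)
  env$just <- list()     # pred -> list(tuple key -> list(rule, body ground))
  env$done <- character()
  check_arities(env)
  env
}

check_arities <- function(env) {
  ar <- new.env(parent = emptyenv())
  note <- function(pred, k, where) {
    prev <- ar[[pred]]
    if (!is.null(prev) && prev != k) {
      da_abort(sprintf("%s: predicate '%s' used with arities %d and %d",
                       where, pred, prev, k), "dietassist_validation_error")
    }
    ar[[pred]] <- k
  }
  for (p in names(env$base)) note(p, ncol(env$base[[p]]), "facts")
  for (r in env$rules) {
    for (a in c(r$body, list(r$head))) {
      if (!a$pred %in% builtin_preds) {
        note(a$pred, length(a$args), sprintf("rule '%s'", r$id))
      }
    }
  }
  invisible()
}

rel_of <- function(env, pred, arity) {
  rel <- env$table[[pred]] %||% env$base[[pred]]
  if (is.null(rel)) return(empty_rel(arity))
  rel
}

# ---- relevance + stratification --------------------------------------------

# predicates reachable from `pred` through rule bodies (the goal-driven part)
relevant_preds <- function(env, pred) {
  seen <- character()
  frontier <- pred
  while (length(frontier)) {
    seen <- union(seen, frontier)
    nxt <- character()
    for (p in frontier) {
      for (r in env$rules_by_head[[p]] %||% list()) {
        nxt <- union(nxt, setdiff(map_chr(r$body, "pred"), builtin_preds))
      }
    }
    frontier <- setdiff(nxt, seen)
  }
  seen
}

# assign strata: a negated dependency must lie in a strictly lower
# stratum; a negative edge inside a recursive clique is rejected
stratify <- function(env, preds) {
  edges <- list() # per pred: data frame(to, neg)
  for (p in preds) {
    rows <- list()
    for (r in env$rules_by_head[[p]] %||% list()) {
      for (a in r$body) {
        if (a$pred %in% builtin_preds) next
        rows[[length(rows) + 1L]] <- data.frame(to = a$pred, neg = a$neg)
      }
    }
    edges[[p]] <- if (length(rows)) unique(bind_rows(rows)) else
      data.frame(to = character(), neg = logical())
  }
  stratum <- stats::setNames(rep(0L, length(preds)), preds)
  for (iter in seq_len(length(preds) + 2L)) {
    changed <- FALSE
    for (p in preds) {
      e <- edges[[p]]
      for (k in seq_len(nrow(e))) {
        q <- e$to[k]
        if (!q %in% preds) next
        need <- stratum[[q]] + if (e$neg[k]) 1L else 0L
        if (stratum[[p]] < need) {
          stratum[[p]] <- need
          changed <- TRUE
        }
      }
    }
    if (!changed) break
    if (iter > length(preds) + 1L) {
      da_abort("rules are not stratified: negation through recursion",
               "dietassist_validation_error")
    }
  }
  stratum
}

# ---- conjunction evaluation -------------------------------------------------

match_positive <- function(env, a, bindings) {
  rel <- rel_of(env, a$pred, length(a$args))
  if (ncol(rel) != length(a$args)) {
    da_abort(sprintf("predicate '%s': arity mismatch", a$pred),
             "dietassist_validation_error")
  }
  keepv <- rep(TRUE, nrow(rel))
  cols <- list() # variable name -> relation column index (first occurrence)
  for (j in seq_along(a$args)) {
    t <- a$args[j]
    if (is_var(t)) {
      v <- substring(t, 2L)
      if (!is.null(cols[[v]])) {
        keepv <- keepv & rel[, j] == rel[, cols[[v]]]
      } else {
        cols[[v]] <- j
      }
    } else {
      keepv <- keepv & rel[, j] == t
    }
  }
  rel <- rel[keepv, , drop = FALSE]
  if (length(cols) == 0L) {
    # fully ground atom: keep or kill the current bindings
    return(if (nrow(rel) > 0L) bindings else bindings[0L, , drop = FALSE])
  }
  df <- unique(as.data.frame(stats::setNames(map(cols, ~ rel[, .x]),
                                             names(cols)),
                             optional = TRUE, check.names = FALSE))
  shared <- intersect(names(bindings), names(df))
  if (ncol(bindings) == 0L) {
    return(if (nrow(bindings) > 0L) df else df[0L, , drop = FALSE])
  }
  unique(merge(bindings, df, by = shared, sort = FALSE))
}

term_values <- function(t, bindings) {
  if (is_var(t)) as.character(bindings[[substring(t, 2L)]])
  else rep(t, nrow(bindings))
}

eval_builtin <- function(a, bindings) {
  if (nrow(bindings) == 0L) return(bindings)
  x <- suppressWarnings(as.numeric(term_values(a$args[1], bindings)))
  y <- suppressWarnings(as.numeric(term_values(a$args[2], bindings)))
  if (a$pred %in% comparison_builtins) {
    ok <- switch(a$pred,
                 lt = x < y, le = x <= y, eq = x == y,
                 ge = x >= y, gt = x > y, ne = x != y)
    ok[is.na(ok)] <- FALSE
    if (a$neg) ok <- !ok
    return(bindings[ok, , drop = FALSE])
  }
  # arithmetic: third term receives (or is checked against) the result
  z <- switch(a$pred, add = x + y, sub = x - y, mul = x * y, div = x / y)
  keepv <- !is.na(z)
  bindings <- bindings[keepv, , drop = FALSE]
  z <- as.character(z[keepv])
  out <- a$args[3]
  if (is_var(out)) {
    v <- substring(out, 2L)
    if (!is.null(bindings[[v]])) {
      bindings[bindings[[v]] == z, , drop = FALSE]
    } else {
      bindings[[v]] <- z
      bindings
    }
  } else {
    bindings[z == out, , drop = FALSE]
  }
}

eval_negated <- function(env, a, bindings) {
  if (nrow(bindings) == 0L) return(bindings)
  rel <- rel_of(env, a$pred, length(a$args))
  have <- tuple_key(rel)
  vals <- map(a$args, term_values, bindings = bindings)
  keys <- do.call(paste, c(vals, sep = "\x1f"))
  bindings[!keys %in% have, , drop = FALSE]
}

atom_ready <- function(a, bound) {
  if (a$pred %in% arith_builtins) {
    inputs <- a$args[1:2]
    return(all(!map_lgl(inputs, is_var) | substring(inputs, 2L) %in% bound))
  }
  if (a$pred %in% comparison_builtins || a$neg) {
    vs <- atom_vars(a)
    return(all(substring(vs, 2L) %in% bound))
  }
  TRUE
}

# evaluate a conjunction left-to-right, deferring built-ins and negated
# atoms until their variables are bound; returns a bindings frame
eval_conjunction <- function(env, body, where = "query") {
  bindings <- true_bindings()
  pending <- body
  while (length(pending)) {
    idx <- which(map_lgl(pending, atom_ready, bound = names(bindings)))[1]
    if (is.na(idx)) {
      da_abort(sprintf(
        "%s: unsafe conjunction (unbound variable in built-in or negated atom)",
        where), "dietassist_validation_error")
    }
    a <- pending[[idx]]
    pending <- pending[-idx]
    bindings <- if (a$pred %in% builtin_preds) {
      eval_builtin(a, bindings)
    } else if (a$neg) {
      eval_negated(env, a, bindings)
    } else {
      match_positive(env, a, bindings)
    }
    if (nrow(bindings) == 0L) return(bindings)
  }
  bindings
}

ground_atom <- function(a, row) {
  args <- map_chr(a$args, function(t) {
    if (is_var(t)) as.character(row[[substring(t, 2L)]]) else t
  })
  atom(a$pred, args, neg = a$neg)
}

# ---- saturation -------------------------------------------------------------

pred_arity_guess <- function(env, pred) {
  rel <- env$table[[pred]] %||% env$base[[pred]]
  if (!is.null(rel)) return(ncol(rel))
  for (r in env$rules) {
    for (a in c(r$body, list(r$head))) {
      if (a$pred == pred) return(length(a$args))
    }
  }
  1L
}

# saturate all predicates relevant to `pred` (tabled; reused across calls)
solve_pred <- function(env, pred) {
  todo <- setdiff(relevant_preds(env, pred), env$done)
  if (length(todo)) {
    strata <- stratify(env, todo)
    for (lev in sort(unique(strata))) {
      level_preds <- names(strata)[strata == lev]
      for (p in level_preds) {
        env$table[[p]] <- env$base[[p]] %||%
          empty_rel(pred_arity_guess(env, p))
      }
      repeat {
        grew <- FALSE
        for (p in level_preds) {
          for (r in env$rules_by_head[[p]] %||% list()) {
            if (apply_rule(env, p, r)) grew <- TRUE
          }
        }
        if (!grew) break
      }
      env$done <- union(env$done, level_preds)
    }
  }
  rel_of(env, pred, pred_arity_guess(env, pred))
}

# evaluate one rule and add its new conclusions; returns TRUE if the
# head relation grew
apply_rule <- function(env, p, r) {
  bindings <- eval_conjunction(env, r$body, where = sprintf("rule '%s'", r$id))
  n <- nrow(bindings)
  if (n == 0L) return(FALSE)
  tuples <- do.call(cbind, map(r$head$args, function(t) {
    if (is_var(t)) as.character(bindings[[substring(t, 2L)]])
    else rep(t, n)
  }))
  cur <- env$table[[p]]
  have <- tuple_key(cur)
  keys <- tuple_key(tuples)
  newi <- which(!duplicated(keys) & !keys %in% have)
  if (length(newi) == 0L) return(FALSE)
  env$table[[p]] <- rbind(cur, tuples[newi, , drop = FALSE])
  for (i in newi) {
    env$just[[p]][[keys[i]]] <-
      list(rule = r, body = map(r$body, ground_atom,
                                row = bindings[i, , drop = FALSE]))
  }
  TRUE
}

# ---- proof trace ------------------------------------------------------------

build_trace <- function(env, goal_ground) {
  rows <- list()
  seen <- character()
  expand <- function(a) {
    if (a$neg || a$pred %in% builtin_preds) return(invisible())
    key <- paste(a$pred, paste(a$args, collapse = "\x1f"), sep = "\x1e")
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    j <- env$just[[a$pred]][[paste(a$args, collapse = "\x1f")]]
    if (is.null(j)) return(invisible()) # base fact: no expansion
    rows[[length(rows) + 1L]] <<- tibble(rule = j$rule$id, subgoal = format(a),
                                         provenance = j$rule$provenance)
    for (b in j$body) expand(b)
    invisible()
  }
  expand(goal_ground)
  if (length(rows) == 0L) {
    tibble(rule = character(), subgoal = character(), provenance = character())
  } else bind_rows(rows)
}

# ---- public operations ------------------------------------------------------

#' Prove a goal by backward chaining
#'
#' Attempts to entail `goal` from the KB's facts plus the rule set.
#' Repeated subgoals are memoized in answer tables, so recursion through
#' cyclic rule graphs terminates; `proven` is `TRUE` exactly when the
#' goal is in the least fixpoint of the rules over the facts.
#'
#' @param goal An [atom()], possibly containing variables.
#' @param kb A `diet_kb`, or `NULL` to reason over `facts` alone.
#' @param rules List of [horn_rule()]s.
#' @param facts Optional list of extra ground [atom()]s.
#' @return A `proof_result`: list with `goal`, `proven`, `bindings`
#'   (named character vector for the lexicographically first answer;
#'   `NULL` when unproven), and `trace` (tibble of
#'   `(rule, subgoal, provenance)` expansions in goal-to-leaf order; one
#'   row per rule application, so direct facts yield an empty trace).
#' @export
prove <- function(goal, kb = NULL, rules = list(), facts = list()) {
  if (!inherits(goal, "atom") || goal$neg) {
    da_abort("goal must be a positive atom", "dietassist_validation_error")
  }
  if (goal$pred %in% builtin_preds) {
    da_abort("goal may not be a built-in", "dietassist_validation_error")
  }
  env <- new_engine(kb, rules, facts)
  solve_pred(env, goal$pred)
  ans <- eval_conjunction(env, list(goal), where = "goal")
  empty_trace <- tibble(rule = character(), subgoal = character(),
                        provenance = character())
  if (nrow(ans) == 0L) {
    return(structure(list(goal = goal, proven = FALSE, bindings = NULL,
                          trace = empty_trace),
                     class = "proof_result"))
  }
  vars <- substring(atom_vars(goal), 2L)
  if (length(vars)) {
    ord <- do.call(order, as.list(ans[vars]))
    row <- ans[ord[1], , drop = FALSE]
    bindings <- stats::setNames(map_chr(vars, ~ as.character(row[[.x]])), vars)
    ground <- ground_atom(goal, row)
  } else {
    bindings <- stats::setNames(character(), character())
    ground <- goal
  }
  structure(list(goal = goal, proven = TRUE, bindings = bindings,
                 trace = build_trace(env, ground)),
            class = "proof_result")
}

#' @export
print.proof_result <- function(x, ...) {
  cat(sprintf("<proof> %s: %s\n", format(x$goal),
              if (x$proven) "PROVEN" else "not proven"))
  if (x$proven && length(x$bindings)) {
    cat("  bindings:", paste(names(x$bindings), x$bindings, sep = " = ",
                             collapse = ", "), "\n")
  }
  if (nrow(x$trace)) {
    cat(sprintf("  trace (%d rule application(s)):\n", nrow(x$trace)))
    for (i in seq_len(nrow(x$trace))) {
      cat(sprintf("    [%s] %s\n", x$trace$rule[i], x$trace$subgoal[i]))
    }
  }
  invisible(x)
}

#' Answer a conjunctive query
#'
#' Grounds every atom of the conjunction against the entailed facts and
#' returns all satisfying substitutions, in deterministic lexicographic
#' order of the bound constants.
#'
#' @param conjunction List of [atom()]s sharing a variable scope.
#' @inheritParams prove
#' @return A tibble with one column per variable and one row per
#'   satisfying substitution (zero rows when unsatisfiable; zero columns
#'   and one row when a fully ground conjunction holds).
#' @export
query <- function(conjunction, kb = NULL, rules = list(), facts = list()) {
  if (inherits(conjunction, "atom")) conjunction <- list(conjunction)
  if (length(conjunction) == 0L) {
    da_abort("empty query", "dietassist_validation_error")
  }
  env <- new_engine(kb, rules, facts)
  for (p in setdiff(unique(map_chr(conjunction, "pred")), builtin_preds)) {
    solve_pred(env, p)
  }
  ans <- eval_conjunction(env, conjunction, where = "query")
  if (ncol(ans) == 0L) return(tibble(.rows = min(nrow(ans), 1L)))
  ans <- unique(as_tibble(ans))
  if (nrow(ans) > 1L) {
    ans <- ans[do.call(order, as.list(ans)), , drop = FALSE]
  }
  ans
}

#' Class subsumption test
#'
#' @param kb A `diet_kb`.
#' @param sub,sup Class identifiers.
#' @return `TRUE` iff `sup` is `sub` itself or in the transitive IS-A
#'   closure of `sub`.
#' @export
is_subsumed <- function(kb, sub, sup) {
  for (cls in c(sub, sup)) {
    if (!cls %in% names(kb$classes)) {
      da_abort(sprintf("unknown class '%s'", cls), "dietassist_lookup_error")
    }
  }
  sub == sup || sup %in% superclasses(kb, sub)
}

#' Check knowledge-base satisfiability
#'
#' A deliberately limited consistency check: reports every individual
#' entailed (through asserted types, IS-A subsumption, and the rule set)
#' to belong to two classes declared disjoint. An empty result means the
#' KB is satisfiable under this check.
#'
#' @param kb A `diet_kb`.
#' @param rules List of [horn_rule()]s (may be empty).
#' @return List of conflicts, each a list with `individual`, `classes`
#'   (the two disjoint classes), and `trace` (entailment trace for both
#'   memberships).
#' @export
check_satisfiability <- function(kb, rules = list()) {
  pairs <- list()
  for (cl in kb$classes) {
    for (d in cl$disjoint_with) {
      key <- paste(sort(c(cl$name, d)), collapse = "\x1f")
      pairs[[key]] <- sort(c(cl$name, d))
    }
  }
  if (length(pairs) == 0L) return(list())
  env <- new_engine(kb, rules)
  conflicts <- list()
  for (pr in pairs[sort(names(pairs))]) {
    a <- solve_pred(env, pr[1])
    b <- solve_pred(env, pr[2])
    both <- sort(intersect(a[, 1], b[, 1]))
    for (ind in both) {
      conflicts[[length(conflicts) + 1L]] <- list(
        individual = ind,
        classes = pr,
        trace = bind_rows(build_trace(env, atom(pr[1], ind)),
                          build_trace(env, atom(pr[2], ind)))
      )
    }
  }
  conflicts
}
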