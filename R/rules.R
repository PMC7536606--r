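#' Horn rules over ontology predicates
#'
#' The rule language is a function-free Datalog subset of SWRL: each rule
#' is a conjunction of body atoms implying a single positive head atom.
#' Atoms are unary class predicates (`Vegetables(?f)`), binary property
#' predicates (`sugar_g(?f, ?s)`), numeric comparison built-ins
#' (`lt`, `le`, `eq`, `ge`, `gt`, `ne`), or arithmetic built-ins
#' (`add`, `sub`, `mul`, `div` -- two bound inputs, third argument bound
#' to the result). Body atoms may be negated (`not Pred(...)`) under
#' stratified negation-as-failure. Rules are *safe*: every head variable
#' and every variable in a negated atom must occur in a positive body
#' atom (or be bound by an arithmetic built-in).
#'
#' @name rules
NULL

comparison_builtins <- c("lt", "le", "eq", "ge", "gt", "ne")
arith_builtins <- c("add", "sub", "mul", "div")
builtin_preds <- c(comparison_builtins, arith_builtins)

symbol_map <- c("<" = "lt", "<=" = "le", "=" = "eq", "==" = "eq",
                ">=" = "ge", ">" = "gt", "!=" = "ne")

is_var <- function(x) startsWith(x, "?")

#' Construct an atom
#'
#' @param pred Predicate identifier; comparison symbols (`<`, `<=`, `=`,
#'   `>=`, `>`, `!=`) are canonicalized to their named built-ins.
#' @param args Character vector of terms; variables are prefixed `?`.
#' @param neg Logical; `TRUE` marks a negated body atom.
#' @return An `atom` object.
#' @export
atom <- function(pred, args, neg = FALSE) {
  stopifnot(is_string(pred), length(args) >= 1L)
  if (pred %in% names(symbol_map)) pred <- symbol_map[[pred]]
  args <- as.character(args)
  if (pred %in% comparison_builtins && length(args) != 2L) {
    da_abort(sprintf("built-in '%s' takes 2 arguments", pred),
             "dietassist_validation_error")
  }
  if (pred %in% arith_builtins && length(args) != 3L) {
    da_abort(sprintf("built-in '%s' takes 3 arguments", pred),
             "dietassist_validation_error")
  }
  structure(list(pred = pred, args = args, neg = isTRUE(neg)), class = "atom")
}

#' @export
format.atom <- function(x, ...) {
  paste0(if (x$neg) "not ", x$pred, "(", paste(x$args, collapse = ", "), ")")
}

#' @export
print.atom <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

atom_vars <- function(a) a$args[map_lgl(a$args, is_var)]

#' Construct a safe Horn rule
#'
#' @param id Rule identifier.
#' @param body List of [atom()]s (the antecedent conjunction).
#' @param head A single positive [atom()] (the consequent).
#' @param provenance Guideline citation string carried into every
#'   conclusion derived through this rule.
#' @return A `horn_rule` object.
#' @export
horn_rule <- function(id, body, head, provenance = "") {
  stopifnot(is_string(id), length(body) >= 1L)
  if (head$neg) {
    da_abort(sprintf("rule '%s': head must be a positive atom", id),
             "dietassist_validation_error")
  }
  if (head$pred %in% builtin_preds) {
    da_abort(sprintf("rule '%s': head may not be a built-in", id),
             "dietassist_validation_error")
  }
  bound <- unique(unlist(map(body, function(a) {
    if (a$neg || a$pred %in% comparison_builtins) return(character())
    if (a$pred %in% arith_builtins) return(a$args[3][is_var(a$args[3])])
    atom_vars(a)
  })))
  need <- unique(c(atom_vars(head),
                   unlist(map(keep(body, "neg"), atom_vars))))
  unsafe <- setdiff(need, bound)
  if (length(unsafe)) {
    da_abort(sprintf("rule '%s' is unsafe: variable(s) %s not bound by a positive body atom",
                     id, paste(unsafe, collapse = ", ")),
             "dietassist_validation_error")
  }
  structure(list(id = id, body = body, head = head,
                 provenance = as.character(provenance)),
            class = "horn_rule")
}

#' @export
format.horn_rule <- function(x, ...) {
  paste0("[", x$id, "] ", paste(map_chr(x$body, format), collapse = " ^ "),
         " -> ", format(x$head))
}

#' @export
print.horn_rule <- function(x, ...) {
  cat(format(x), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

parse_atom_text <- function(txt, where) {
  txt <- trimws(txt)
  neg <- FALSE
  if (grepl("^not\\s+", txt)) {
    neg <- TRUE
    txt <- sub("^not\\s+", "", txt)
  }
  m <- regmatches(txt, regexec("^([A-Za-z0-9_<>=!.-]+)\\(([^()]*)\\)$", txt))[[1]]
  if (length(m) != 3L) {
    da_abort(sprintf("%s: cannot parse atom '%s'", where, txt),
             "dietassist_format_error")
  }
  args <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
  if (length(args) == 0L || any(!nzchar(args))) {
    da_abort(sprintf("%s: empty argument in atom '%s'", where, txt),
             "dietassist_format_error")
  }
  atom(m[2], args, neg = neg)
}

#' Parse rules from the plain-text SWRL-like format
#'
#' One rule per line:
#' ```
#' rule_id: Body1(?x) ^ Body2(?x, ?v) ^ gt(?v, 10) -> Head(?x) @ "citation"
#' ```
#' The `rule_id:` prefix and `@ "..."` provenance suffix are optional
#' (ids default to `r<line>`); `#` starts a comment. Parse errors cite
#' the offending line number.
#'
#' @param path File path, or `NULL` if `text` is given.
#' @param text Character vector of lines (alternative to `path`).
#' @return List of [horn_rule()]s.
#' @export
parse_rules <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) {
      da_abort(sprintf("rule file not found: %s", path), "dietassist_format_error")
    }
    text <- readLines(path, warn = FALSE)
  }
  rules <- list()
  for (i in seq_along(text)) {
    ln <- trimws(sub("#.*$", "", text[i]))
    if (!nzchar(ln)) next
    where <- sprintf("rule file line %d", i)

    prov <- ""
    pm <- regmatches(ln, regexec("@\\s*\"([^\"]*)\"\\s*$", ln))[[1]]
    if (length(pm) == 2L) {
      prov <- pm[2]
      ln <- trimws(sub("@\\s*\"[^\"]*\"\\s*$", "", ln))
    }

    id <- sprintf("r%d", i)
    im <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(im) == 3L) {
      id <- im[2]
      ln <- im[3]
    }

    parts <- strsplit(ln, "->", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      da_abort(sprintf("%s: expected 'body -> head', got '%s'", where, ln),
               "dietassist_format_error")
    }
    body_txt <- strsplit(parts[1], "^", fixed = TRUE)[[1]]
    body <- map(body_txt, parse_atom_text, where = where)
    head <- parse_atom_text(parts[2], where = where)
    rules[[length(rules) + 1L]] <- horn_rule(id, body, head, provenance = prov)
  }
  rules
}

#' Parse rules from the equivalent JSON form
#'
#' Accepts `[{"id":..., "body": [{"pred":..., "args": [...],
#' "neg": false}], "head": {...}, "provenance": ...}, ...]`.
#'
#' @param path JSON file path.
#' @return List of [horn_rule()]s.
#' @export
parse_rules_json <- function(path) {
  x <- jsonlite::read_json(path)
  mk_atom <- function(a) atom(a$pred, unlist(a$args), neg = isTRUE(a$neg))
  map(x, function(r) {
    horn_rule(r$id, body = map(r$body, mk_atom), head = mk_atom(r$head),
              provenance = r$provenance %||% "")
  })
}
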