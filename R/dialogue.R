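#' Finite-state dialogue management
#'
#' The conversation layer mirrors a voice-assistant stack in text mode:
#' utterance intent detection with ontology/synonym expansion (UID), a
#' finite-state dialogue manager with slot filling and a two-tier
#' context store (DM), and templated response generation adapted to the
#' caregiver's education level (RG). Each of the five service categories
#' has its own state transition graph starting at `S0`; dialogue history
#' is the path of visited state ids.
#'
#' @name dialogue
NULL

#' Load the intent registry
#'
#' @param path YAML registry; defaults to the packaged one, which
#'   defines the five service categories (proper-diet tips,
#'   eating-challenge handling, food/nutrition explanation, meal
#'   suggestion, diet-history recall).
#' @return List of `intent` objects.
#' @export
load_intent_registry <- function(path = system.file("extdata", "intents.yaml",
                                                    package = "dietassist")) {
  y <- yaml::read_yaml(path)
  map(y$intents, function(it) {
    slots <- map(it$slots %||% list(), function(s) {
      list(name = s$name, type = s$type, required = isTRUE(s$required),
           prompt = s$prompt, prefill = s$prefill %||% NULL)
    })
    if (anyDuplicated(map_chr(slots, "name"))) {
      da_abort(sprintf("intent '%s': duplicate slot names", it$name),
               "dietassist_validation_error")
    }
    if (length(it$utterances) < 1L) {
      da_abort(sprintf("intent '%s': needs at least one sample utterance", it$name),
               "dietassist_validation_error")
    }
    structure(list(name = it$name, category = it$category, slots = slots,
                   utterances = unlist(it$utterances)),
              class = "intent")
  })
}

#' Service categories present in a registry
#' @param registry Output of [load_intent_registry()].
#' @return Sorted character vector of category names.
#' @export
intent_categories <- function(registry) {
  sort(unique(map_chr(registry, "category")))
}

#' Load the per-category state transition graphs
#' @param path YAML file; defaults to the packaged graphs.
#' @return Named list (by category) of graphs; each graph is a named
#'   list of states with `id`, `action`, `transitions`, `terminal`.
#' @export
load_state_graphs <- function(path = system.file("extdata", "state_graphs.yaml",
                                                 package = "dietassist")) {
  y <- yaml::read_yaml(path)
  map(y, function(g) {
    states <- map(g$states, function(s) {
      list(id = s$id, action = s$action,
           transitions = map(s$transitions %||% list(),
                             ~ list(when = .x$when, to = .x$to)),
           terminal = isTRUE(s$terminal))
    })
    names(states) <- map_chr(states, "id")
    if (!"S0" %in% names(states)) {
      da_abort("state graph must declare S0", "dietassist_validation_error")
    }
    for (s in states) {
      bad <- setdiff(map_chr(s$transitions, "to"), names(states))
      if (length(bad)) {
        da_abort(sprintf("state '%s' targets undeclared state(s): %s",
                         s$id, paste(bad, collapse = ", ")),
                 "dietassist_validation_error")
      }
    }
    states
  })
}

#' Load response templates
#' @param path YAML file mapping action -> education tier -> template.
#' @return Nested named list.
#' @export
load_templates <- function(path = system.file("extdata", "templates.yaml",
                                              package = "dietassist")) {
  yaml::read_yaml(path)
}

# ---- utterance interpretation ----------------------------------------------

# replace multi-word vocabulary terms (longest first) by canonical
# concept ids; returns list(tokens = expanded tokens, concepts = tibble)
expand_utterance <- function(tokens, vocabulary) {
  out <- character()
  hits <- list()
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    matched <- FALSE
    for (len in 3:1) {
      if (i + len - 1L > n) next
      gram <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      concept <- unname(vocabulary[gram])
      if (!is.na(concept) && length(concept)) {
        out <- c(out, concept)
        hits[[length(hits) + 1L]] <- tibble(term = gram, concept = concept)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      out <- c(out, tokens[i])
      i <- i + 1L
    }
  }
  list(tokens = out,
       concepts = if (length(hits)) bind_rows(hits) else
         tibble(term = character(), concept = character()))
}

word_numbers <- c(one = 1, two = 2, three = 3, four = 4, five = 5,
                  six = 6, seven = 7, eight = 8, nine = 9, ten = 10)

extract_numbers <- function(tokens) {
  vals <- suppressWarnings(as.numeric(tokens))
  wi <- match(tokens, names(word_numbers))
  vals[!is.na(wi)] <- word_numbers[wi[!is.na(wi)]]
  vals
}

# pull a value of the slot's semantic type out of an interpreted utterance
extract_slot_value <- function(type, tokens, concepts, kb) {
  switch(type,
    food_concept = {
      for (cid in concepts$concept) {
        rc <- resolve_concept(kb, cid)
        if (is.null(rc)) next
        if (rc$kind == "food") return(rc$id)
        if (rc$kind == "class" &&
            "food" %in% norm_class_term(concept_ancestry(kb, rc))) {
          return(rc$id)
        }
      }
      NULL
    },
    meal_type = {
      mapped <- c(breakfast = "breakfast", lunch = "lunch", dinner = "dinner",
                  snack = "snack", supper = "dinner", tonight = "dinner",
                  morning = "breakfast")
      hit <- mapped[tokens]
      hit <- hit[!is.na(hit)]
      if (length(hit)) unname(hit[1]) else NULL
    },
    count = {
      vals <- extract_numbers(tokens)
      anchored <- which(!is.na(vals) &
                          c(tokens[-1], "") %in% c("servings", "serving",
                                                   "people", "persons", "portions"))
      idx <- if (length(anchored)) anchored[1] else {
        # a bare integer not attached to a time word
        free <- which(!is.na(vals) & vals == floor(vals) &
                        !c(tokens[-1], "") %in% c("minutes", "minute", "min", "mins"))
        if (length(free)) free[1] else NA_integer_
      }
      if (is.na(idx)) NULL else as.integer(vals[idx])
    },
    minutes = {
      vals <- extract_numbers(tokens)
      idx <- which(!is.na(vals) &
                     c(tokens[-1], "") %in% c("minutes", "minute", "min", "mins"))
      if (length(idx)) vals[idx[1]] else NULL
    },
    window = {
      mapped <- c(today = "day", daily = "day", day = "day",
                  week = "week", weekly = "week")
      hit <- mapped[tokens]
      hit <- hit[!is.na(hit)]
      if (length(hit)) unname(hit[1]) else NULL
    },
    number = {
      vals <- extract_numbers(tokens)
      idx <- which(!is.na(vals))
      if (length(idx)) vals[idx[1]] else NULL
    },
    da_abort(sprintf("unknown slot type '%s'", type), "dietassist_validation_error")
  )
}

jaccard <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0L) return(0)
  length(intersect(a, b)) / length(u)
}

#' Detect the user's intent
#'
#' Normalizes the utterance (lowercase, punctuation stripped), expands
#' it with synonyms and ontology concepts from the matching vocabulary,
#' extracts candidate slot values, and scores the expanded token set
#' against each intent's sample utterances by Jaccard token overlap
#' (slot placeholders instantiated with the extracted values). The best
#' intent is returned when its score reaches `threshold`; otherwise
#' `NULL` (no match), which triggers a clarification action downstream.
#'
#' @param utterance User text.
#' @param registry Intent registry ([load_intent_registry()]).
#' @param vocabulary Term-to-concept map ([build_matching_vocabulary()]).
#' @param kb The KB (used to type-check candidate slot values).
#' @param threshold Minimum similarity score in (0, 1]; default 0.5.
#' @return `NULL`, or a list with `intent`, `slots` (named list of
#'   extracted values), and `score`.
#' @export
detect_intent <- function(utterance, registry, vocabulary, kb, threshold = 0.5) {
  if (length(registry) == 0L) {
    da_abort("empty intent registry", "dietassist_validation_error")
  }
  tokens <- tokenize(utterance %||% "")
  if (length(tokens) == 0L) return(NULL)
  ex <- expand_utterance(tokens, vocabulary)

  best <- NULL
  for (it in registry[order(map_chr(registry, "name"))]) {
    slots <- list()
    for (s in it$slots) {
      v <- extract_slot_value(s$type, ex$tokens, ex$concepts, kb)
      if (!is.null(v)) slots[[s$name]] <- v
    }
    score <- max(map_dbl(it$utterances, function(u) {
      tt <- tokenize(u)
      for (nm in names(slots)) {
        tt[tt == paste0("{", nm, "}")] <- as.character(slots[[nm]])
      }
      jaccard(unique(ex$tokens), unique(tt))
    }))
    if (is.null(best) || score > best$score) {
      best <- list(intent = it, slots = slots, score = score)
    }
  }
  if (best$score >= threshold) best else NULL
}

# ---- sessions and context ---------------------------------------------------

#' Create a dialogue session
#'
#' A session tracks the finite-state position (`current_state`), the
#' state-path history (always starting at `S0`), slot bindings, the
#' context store, the turn counter, and the recipes rejected so far.
#' Long-term context entries for the patient's allergies, stage, and
#' preferences are installed at creation and never expire within the
#' session; short-term entries expire after `short_expiry` turns.
#'
#' @param patient A [patient_profile()].
#' @param caregiver A [caregiver_profile()].
#' @param id Session identifier.
#' @param max_turns Turn budget before the dialogue is marked failed
#'   (default 20).
#' @param short_expiry Default expiry (in turns) for short-term context
#'   entries (default 5).
#' @return A `dialogue_session` object (an environment).
#' @export
dialogue_session <- function(patient, caregiver, id = "session-1",
                             max_turns = 20, short_expiry = 5) {
  s <- new.env(parent = emptyenv())
  s$id <- id
  s$patient <- patient
  s$caregiver <- caregiver
  s$current_state <- "S0"
  s$history <- "S0"
  s$category <- NULL
  s$intent <- NULL
  s$slots <- list()
  s$context <- list()
  s$turn_count <- 0L
  s$rejected <- character()
  s$offered <- character()
  s$last_offer <- NULL
  s$retries <- 0L
  s$tip_cursor <- 0L
  s$awaiting <- NULL
  s$done <- FALSE
  s$failed <- FALSE
  s$max_turns <- max_turns
  s$short_expiry <- short_expiry
  class(s) <- c("dialogue_session", "environment")
  context_set(s, "patient_allergies", patient$allergies, scope = "long")
  context_set(s, "adrd_stage", patient$adrd_stage, scope = "long")
  context_set(s, "patient_preferences", patient$preferences, scope = "long")
  s
}

#' Set a context entry
#' @param session A [dialogue_session()].
#' @param key Entry key.
#' @param value Entry value.
#' @param scope `"short"` (expires after `expires_after` turns) or
#'   `"long"` (kept for the whole session).
#' @param expires_after Turns until a short entry expires; defaults to
#'   the session's `short_expiry`.
#' @return The session, invisibly.
#' @export
context_set <- function(session, key, value, scope = c("short", "long"),
                        expires_after = NULL) {
  scope <- match.arg(scope)
  expires_after <- if (scope == "long") Inf else
    (expires_after %||% session$short_expiry)
  if (scope == "short" && (!is_num(expires_after) || expires_after <= 0)) {
    da_abort("short-term context needs finite expires_after > 0",
             "dietassist_validation_error")
  }
  session$context[[key]] <- list(key = key, value = value, scope = scope,
                                 expires_after = expires_after)
  invisible(session)
}

#' Get a context entry's value (or `NULL`)
#' @param session A [dialogue_session()].
#' @param key Entry key.
#' @export
context_get <- function(session, key) {
  session$context[[key]]$value
}

#' Expire short-term context
#'
#' Called at the end of each turn: decrements every short-term entry's
#' remaining lifetime and drops entries that reach zero. Long-term
#' entries are untouched.
#'
#' @param session A [dialogue_session()].
#' @return The session, invisibly.
#' @export
expire_context <- function(session) {
  keep <- list()
  for (e in session$context) {
    if (e$scope == "long") {
      keep[[e$key]] <- e
    } else {
      e$expires_after <- e$expires_after - 1L
      if (e$expires_after > 0) keep[[e$key]] <- e
    }
  }
  session$context <- keep
  invisible(session)
}

# ---- slot filling -----------------------------------------------------------

profile_lookup <- function(path, patient, caregiver) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  obj <- switch(parts[1], patient = patient, caregiver = caregiver, NULL)
  if (is.null(obj)) return(NULL)
  obj[[parts[2]]]
}

#' Merge slot answers into a session
#'
#' Applies profile prefills for unfilled slots that declare one, then
#' merges extracted answers. Over-answering (an utterance supplying
#' several slots at once) fills them all in one turn; an
#' already-confirmed slot is never overwritten.
#'
#' @param session A [dialogue_session()].
#' @param intent The active intent.
#' @param answers Named list of extracted slot values (possibly empty).
#' @return The session, invisibly.
#' @export
fill_slots <- function(session, intent, answers = list()) {
  for (s in intent$slots) {
    if (!is.null(session$slots[[s$name]])) next
    if (!is.null(s$prefill)) {
      v <- profile_lookup(s$prefill, session$patient, session$caregiver)
      if (!is.null(v)) session$slots[[s$name]] <- v
    }
  }
  for (nm in names(answers)) {
    if (is.null(session$slots[[nm]])) session$slots[[nm]] <- answers[[nm]]
  }
  invisible(session)
}

next_unfilled_slot <- function(session, intent) {
  for (s in intent$slots) {
    if (s$required && is.null(session$slots[[s$name]])) return(s)
  }
  NULL
}

slots_complete <- function(session, intent) {
  is.null(next_unfilled_slot(session, intent))
}

# ---- state transitions ------------------------------------------------------

condition_holds <- function(cond, session, event) {
  if (cond == "else") return(TRUE)
  if (cond == "intent") return(identical(event$kind, "intent"))
  if (startsWith(cond, "intent:")) {
    return(identical(event$kind, "intent") &&
             identical(event$intent$name, sub("^intent:", "", cond)))
  }
  if (cond == "slots_complete") return(isTRUE(event$slots_complete))
  if (cond %in% c("accept", "reject", "no_match")) {
    return(identical(event$kind, cond))
  }
  if (startsWith(cond, "slot:")) {
    kv <- strsplit(sub("^slot:", "", cond), "=", fixed = TRUE)[[1]]
    return(identical(as.character(session$slots[[kv[1]]] %||% ""), kv[2]))
  }
  if (startsWith(cond, "context:")) {
    return(!is.null(context_get(session, sub("^context:", "", cond))))
  }
  da_abort(sprintf("unknown transition condition '%s'", cond),
           "dietassist_validation_error")
}

#' Compute the successor dialogue state
#'
#' Evaluates the current state's transition conditions in declaration
#' order against the interpreted input event; the first matching
#' condition wins. Unmatched input self-loops with a re-prompt action.
#'
#' @param session A [dialogue_session()].
#' @param event Interpreted input: list with `kind` (`intent`, `answer`,
#'   `accept`, `reject`, `no_match`) plus `intent`/`slots`/
#'   `slots_complete` as applicable.
#' @param graph A single category's state graph.
#' @return List with `state` (successor id) and `action` (the successor
#'   state's entry action, or `"reprompt"` on a self-loop).
#' @export
next_state <- function(session, event, graph) {
  cur <- graph[[session$current_state]]
  if (is.null(cur)) {
    # corrupted state id: reset to the start of this graph
    session$current_state <- "S0"
    session$history <- c(session$history, "S0")
    return(list(state = "S0", action = "reprompt"))
  }
  for (tr in cur$transitions) {
    if (condition_holds(tr$when, session, event)) {
      session$current_state <- tr$to
      session$history <- c(session$history, tr$to)
      return(list(state = tr$to, action = graph[[tr$to]]$action))
    }
  }
  session$history <- c(session$history, cur$id)
  list(state = cur$id, action = "reprompt")
}

# ---- response generation ----------------------------------------------------

#' Render a response for an action
#'
#' Picks the action's template for the caregiver's education tier and
#' interpolates the content payload. Basic-tier templates use short
#' sentences without technical nutrient terms or percentages; the
#' advanced tier includes the numeric rationale. Deterministic for
#' fixed inputs.
#'
#' @param action Action name (must be registered in the templates).
#' @param payload Named list of values referenced by the template.
#' @param caregiver A [caregiver_profile()] (selects the tier).
#' @param templates Template set ([load_templates()]).
#' @return Response text.
#' @export
generate_response <- function(action, payload, caregiver,
                              templates = load_templates()) {
  tpl_set <- templates[[action]]
  if (is.null(tpl_set)) {
    da_abort(sprintf("no template registered for action '%s'", action),
             "dietassist_template_error")
  }
  tpl <- tpl_set[[caregiver$education_level]] %||% tpl_set[["standard"]]
  if (is.null(tpl)) {
    da_abort(sprintf("no template for action '%s' at tier '%s'",
                     action, caregiver$education_level),
             "dietassist_template_error")
  }
  interpolate(tpl, payload)
}
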