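#' Assemble the assistant
#'
#' Bundles the knowledge base, guideline rules, intent registry, state
#' graphs, response templates, tip bank, and matching vocabulary into
#' one application object used by the dialogue loop, the evaluation
#' harness, and the command-line interface.
#'
#' @param kb A `diet_kb`.
#' @param rules Guideline rules; default the packaged rule base.
#' @param registry Intent registry; default the packaged five-category
#'   registry.
#' @param graphs State graphs; default the packaged ones.
#' @param templates Response templates; default the packaged ones.
#' @param tips Tip bank; default the packaged one.
#' @param top_classes Top-level classes anchoring the matching
#'   vocabulary; defaults to every root class present in the KB.
#' @param threshold Intent similarity threshold (default 0.5).
#' @param max_turns Dialogue turn budget (default 20).
#' @return A `diet_app` list.
#' @export
diet_app <- function(kb, rules = default_guideline_rules(),
                     registry = load_intent_registry(),
                     graphs = load_state_graphs(),
                     templates = load_templates(),
                     tips = load_tip_bank(),
                     top_classes = NULL, threshold = 0.5, max_turns = 20) {
  if (is.null(top_classes)) {
    top_classes <- names(kb$classes)[map_lgl(kb$classes,
                                             ~ length(.x$parents) == 0L)]
  }
  structure(
    list(kb = kb, rules = rules, registry = registry, graphs = graphs,
         templates = templates, tips = tips,
         vocabulary = build_matching_vocabulary(kb, top_classes),
         threshold = threshold, max_turns = max_turns,
         history = new.env(parent = emptyenv())),
    class = "diet_app"
  )
}

accept_words <- c("yes", "yeah", "yep", "ok", "okay", "sure", "sounds",
                  "good", "great", "perfect", "thanks", "thank", "please")
reject_words <- c("no", "nope", "not", "dont", "don t", "another", "else",
                  "different", "rather", "reject", "change")

# classify one user utterance into a dialogue event
interpret_input <- function(app, session, utterance) {
  tokens <- tokenize(utterance %||% "")
  if (length(tokens) == 0L) return(list(kind = "no_match"))

  # pending elicited datum outside the slot system (e.g. the EER)
  if (identical(session$awaiting, "eer")) {
    vals <- extract_numbers(tokens)
    v <- vals[!is.na(vals)][1]
    if (!is.na(v) && !is.null(v)) {
      session$patient$eer <- v
      session$awaiting <- NULL
      # re-run the offer state without recording a rejection
      return(list(kind = "reject", no_rejection = TRUE, slots_complete = TRUE))
    }
  }

  graph <- active_graph(app, session)
  at_offer <- identical(graph[[session$current_state]]$action, "offer") &&
    !is.null(session$last_offer)
  if (at_offer) {
    if (any(tokens %in% reject_words)) return(list(kind = "reject"))
    if (any(tokens %in% accept_words)) return(list(kind = "accept"))
  }

  di <- detect_intent(utterance, app$registry, app$vocabulary, app$kb,
                      threshold = app$threshold)
  if (!is.null(di)) {
    same <- !is.null(session$intent) &&
      identical(di$intent$name, session$intent$name)
    if (!same) return(list(kind = "intent", intent = di$intent, slots = di$slots))
    return(list(kind = "answer", slots = di$slots))
  }

  # try to read the utterance as (over-)answers to the open slots
  if (!is.null(session$intent) && !slots_complete(session, session$intent)) {
    ex <- expand_utterance(tokens, app$vocabulary)
    answers <- list()
    for (s in session$intent$slots) {
      if (!is.null(session$slots[[s$name]])) next
      v <- extract_slot_value(s$type, ex$tokens, ex$concepts, app$kb)
      if (!is.null(v)) answers[[s$name]] <- v
    }
    if (length(answers)) return(list(kind = "answer", slots = answers))
  }
  list(kind = "no_match")
}

active_graph <- function(app, session) {
  app$graphs[[session$category %||% names(app$graphs)[1]]]
}

# ---- action handlers --------------------------------------------------------

fmt0 <- function(x) formatC(x, format = "f", digits = 0)

handle_answer <- function(app, session) {
  intent <- session$intent$name
  food_id <- session$slots$food
  f <- app$kb$foods[[food_id]]
  label <- display_name(app$kb, food_id)
  if (identical(intent, "FoodSuitability")) {
    v <- check_food_suitability(food_id, session$slots$meal, session$patient,
                                app$kb, app$rules)
    context_set(session, "last_food", food_id, scope = "short")
    context_set(session, "last_verdict", v$suitable, scope = "short")
    phrase <- switch(v$suitable, recommended = "a good choice",
                     not_recommended = "not recommended",
                     caution = "acceptable in moderation")
    payload <- list(food = label, meal = session$slots$meal,
                    verdict_phrase = phrase,
                    reason = paste(v$reasons$explanation, collapse = "; "),
                    reason_simple = v$reasons$explanation[1])
    if (!is.null(f)) {
      payload$energy_kcal <- fmt0(f$nutrients[["energy_kcal"]])
      payload$sugar_g <- fmt0(f$nutrients[["sugar_g"]])
      payload$sugar_pct <- fmt0(
        if (f$nutrients[["energy_kcal"]] > 0)
          100 * 4 * f$nutrients[["sugar_g"]] / f$nutrients[["energy_kcal"]] else 0)
    } else {
      payload$energy_kcal <- "-"; payload$sugar_g <- "-"; payload$sugar_pct <- "-"
    }
    return(list(action = "suitability_verdict", payload = payload, verdict = v))
  }
  # ExplainFood
  if (is.null(f)) {
    return(list(action = "clarify", payload = list()))
  }
  cls <- mind_classify(app$kb, food_id)
  reason <- switch(cls,
    encourage = sprintf("%s is encouraged by the MIND diet.", label),
    limit = sprintf("The MIND diet suggests limiting %s.", label),
    sprintf("%s is neither specifically encouraged nor limited by the MIND diet.",
            label))
  context_set(session, "last_food", food_id, scope = "short")
  list(action = "explain_food",
       payload = list(food = label,
                      energy_kcal = fmt0(f$nutrients[["energy_kcal"]]),
                      protein_g = fmt0(f$nutrients[["protein_g"]]),
                      carb_g = fmt0(f$nutrients[["carb_g"]]),
                      fat_g = fmt0(f$nutrients[["fat_g"]]),
                      sugar_g = fmt0(f$nutrients[["sugar_g"]]),
                      fiber_g = fmt0(f$nutrients[["fiber_g"]]),
                      sodium_mg = fmt0(f$nutrients[["sodium_mg"]]),
                      reason = reason, reason_simple = reason))
}

handle_offer <- function(app, session, event) {
  if (identical(event$kind, "reject") && !isTRUE(event$no_rejection) &&
      !is.null(session$last_offer)) {
    session$rejected <- union(session$rejected, session$last_offer)
    session$last_offer <- NULL
  }
  if (identical(session$intent$name, "SuggestSnack")) {
    res <- suggest_snack(session$patient, session$caregiver, app$kb,
                         app$rules, session)
    if (is.null(res$food)) {
      return(list(action = "none_available",
                  payload = list(reason = res$verdict$reasons$explanation[1],
                                 reason_simple = "Nothing fits his needs right now.")))
    }
    session$last_offer <- res$food$id
    session$offered <- union(session$offered, res$food$id)
    reason <- paste(res$verdict$reasons$explanation, collapse = "; ")
    return(list(action = "offer_snack",
                payload = list(food = res$food$name, reason = reason,
                               reason_simple = res$verdict$reasons$explanation[1],
                               energy_kcal = fmt0(res$food$nutrients[["energy_kcal"]]),
                               sugar_g = fmt0(res$food$nutrients[["sugar_g"]]))))
  }
  # RecommendRecipe
  res <- tryCatch(
    recommend_recipe(session$slots, session$patient, session$caregiver,
                     app$kb, app$rules, session),
    dietassist_missing_data_error = function(e) e
  )
  if (inherits(res, "dietassist_missing_data_error")) {
    session$awaiting <- "eer"
    return(list(action = "missing_data",
                payload = list(prompt = "To size a diabetic dinner I need his daily energy requirement in calories. What is it?")))
  }
  if (is.null(res$recipe)) {
    return(list(action = "none_available",
                payload = list(reason = res$reason,
                               reason_simple = "Nothing fits all his needs right now.")))
  }
  r <- res$recipe
  nut <- recipe_nutrients(r, app$kb)
  session$last_offer <- r$id
  session$offered <- union(session$offered, r$id)
  context_set(session, "last_recipe", r$id, scope = "short")
  list(action = "offer_recipe",
       payload = list(recipe = r$name,
                      energy_kcal = fmt0(nut[["energy_kcal"]]),
                      protein_pct = fmt0(100 * 4 * nut[["protein_g"]] / nut[["energy_kcal"]]),
                      sugar_pct = fmt0(100 * 4 * nut[["sugar_g"]] / nut[["energy_kcal"]]),
                      prep_time = fmt0(r$prep_time),
                      reason = res$rationale$explanation[1]),
       recommendation = r$id)
}

handle_tip <- function(app, session) {
  category <- if (identical(session$intent$name, "EatingChallengeTip"))
    "eating_challenge" else "proper_diet"
  tip <- get_tip(app$tips, category, session$patient$adrd_stage,
                 session$caregiver$education_level, session$tip_cursor)
  session$tip_cursor <- session$tip_cursor + 1L
  list(action = "tip", payload = list(tip = tip$text), tip_id = tip$id)
}

handle_history <- function(app, session) {
  pid <- session$patient$id %||% "patient"
  hist <- app$history[[pid]]
  win <- session$slots$window %||% "day"
  anchor <- context_get(session, "today") %||% Sys.Date()
  rec <- recall_history(hist, win, anchor)
  n <- nrow(rec$records)
  summary <- if (n == 0L) {
    sprintf("I have no meals recorded for that %s.", win)
  } else {
    sprintf("Over that %s he had %d recorded meal(s): %s.", win, n,
            paste(unique(rec$records$meal), collapse = ", "))
  }
  list(action = "history",
       payload = list(summary = summary, total_kcal = fmt0(rec$total_energy),
                      n = n))
}

perform_action <- function(app, session, action_label, event) {
  switch(action_label,
    greet = list(action = "greet", payload = list()),
    elicit_slot = {
      slot <- next_unfilled_slot(session, session$intent)
      list(action = "elicit_slot", payload = list(prompt = slot$prompt))
    },
    reprompt = {
      prompt <- if (!is.null(session$intent)) {
        s <- next_unfilled_slot(session, session$intent)
        if (!is.null(s)) s$prompt else "How else can I help?"
      } else "How can I help?"
      list(action = if (identical(event$kind, "no_match") &&
                        is.null(session$intent)) "clarify" else "reprompt",
           payload = list(prompt = prompt))
    },
    answer = handle_answer(app, session),
    offer = handle_offer(app, session, event),
    tip = handle_tip(app, session),
    history = handle_history(app, session),
    close = list(action = "close", payload = list()),
    apologize = list(action = "apologize", payload = list()),
    da_abort(sprintf("unknown dialogue action '%s'", action_label),
             "dietassist_validation_error")
  )
}

# ---- the turn loop ----------------------------------------------------------

#' Process one dialogue turn
#'
#' Interprets the utterance (intent detection, accept/reject at an
#' offer, slot answers), advances the finite-state graph, executes the
#' entry action of the successor state through the back-end services,
#' expires short-term context, and renders the response for the
#' caregiver's education tier.
#'
#' @param app A [diet_app()].
#' @param session A [dialogue_session()].
#' @param utterance User text for this turn.
#' @return List with `session`, `state`, `action` (concrete action
#'   emitted), `response` (text), and optionally `recommendation`
#'   (recipe id offered this turn).
#' @export
dm_step <- function(app, session, utterance) {
  session$turn_count <- session$turn_count + 1L
  event <- interpret_input(app, session, utterance)

  progress <- event$kind %in% c("intent", "accept", "reject") ||
    (identical(event$kind, "answer") && length(event$slots %||% list()) > 0L)

  if (event$kind == "intent") {
    session$intent <- event$intent
    session$category <- event$intent$category
    session$slots <- list()
    session$retries <- 0L
    if (!session$current_state %in% names(active_graph(app, session))) {
      session$current_state <- "S0"
    }
    fill_slots(session, session$intent, event$slots)
    event$slots_complete <- slots_complete(session, session$intent)
  } else if (event$kind == "answer" && !is.null(session$intent)) {
    fill_slots(session, session$intent, event$slots %||% list())
    event$slots_complete <- slots_complete(session, session$intent)
  }

  graph <- active_graph(app, session)
  ns <- next_state(session, event, graph)

  # a state that elicits slots is skipped when nothing is left to elicit
  guard <- 0L
  while (ns$action == "elicit_slot" && !is.null(session$intent) &&
         slots_complete(session, session$intent) && guard < 5L) {
    ns <- next_state(session, list(kind = "internal", slots_complete = TRUE),
                     graph)
    guard <- guard + 1L
  }

  if (!progress && ns$action %in% c("elicit_slot", "reprompt")) {
    session$retries <- session$retries + 1L
  } else if (progress) {
    session$retries <- 0L
  }
  if (session$retries > 3L) {
    session$intent <- NULL
    session$slots <- list()
    session$retries <- 0L
    session$current_state <- "S0"
    session$history <- c(session$history, "S0")
    out <- list(action = "apologize", payload = list())
  } else {
    out <- perform_action(app, session, ns$action, event)
  }

  if (isTRUE(graph[[session$current_state]]$terminal)) session$done <- TRUE
  if (session$turn_count >= session$max_turns && !session$done) {
    session$failed <- TRUE
  }
  expire_context(session)
  resp <- generate_response(out$action, out$payload, session$caregiver,
                            app$templates)
  list(session = session, state = session$current_state, action = out$action,
       response = resp, recommendation = out$recommendation %||% NULL)
}

#' Run an interactive (or replayed) chat session
#'
#' Opens with a greeting, then feeds each input line through
#' [dm_step()] until a quit word, a terminal dialogue state, or the
#' turn budget. With `lines = NULL` reads interactively from stdin.
#'
#' @param app A [diet_app()].
#' @param patient,caregiver Profiles.
#' @param lines Character vector of user inputs to replay, or `NULL`
#'   for interactive stdin.
#' @param quiet Suppress console printing.
#' @return Transcript tibble (`turn`, `user`, `state`, `action`,
#'   `response`), invisibly when interactive.
#' @export
chat_session <- function(app, patient, caregiver, lines = NULL, quiet = FALSE) {
  session <- dialogue_session(patient, caregiver, max_turns = app$max_turns)
  say <- function(x) if (!quiet) cat("assistant>", x, "\n")
  greeting <- generate_response("greet", list(), caregiver, app$templates)
  say(greeting)
  transcript <- list(tibble(turn = 0L, user = "", state = "S0",
                            action = "greet", response = greeting))
  quit_words <- c("quit", "exit", "bye", "goodbye", "stop")
  interactive_mode <- is.null(lines)
  i <- 0L
  repeat {
    line <- if (interactive_mode) {
      if (!quiet) cat("caregiver> ")
      x <- tryCatch(readLines(con = "stdin", n = 1L), error = function(e) character())
      if (length(x) == 0L) break
      x
    } else {
      i <- i + 1L
      if (i > length(lines)) break
      lines[i]
    }
    if (tolower(trimws(line)) %in% quit_words) break
    step <- dm_step(app, session, line)
    say(step$response)
    transcript[[length(transcript) + 1L]] <-
      tibble(turn = session$turn_count, user = line, state = step$state,
             action = step$action, response = step$response)
    if (session$done || session$failed) break
  }
  out <- bind_rows(transcript)
  if (interactive_mode) invisible(out) else out
}
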