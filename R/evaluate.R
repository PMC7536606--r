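#' Scripted-conversation evaluation harness
#'
#' Replays JSONL conversation scripts against the assistant and scores
#' them with the two dialogue metrics: the dialogue success rate (the
#' share of conversations that produced a satisfying response within the
#' maximum-turn threshold, default 20) and the recommendation
#' correctness rate (the share of substantive responses consistent with
#' the guidelines and the user profiles, judged by an automated checker
#' that re-derives each recommendation's constraint status).
#'
#' @name evaluation
NULL

#' Read a conversation script (JSONL)
#'
#' Line 1 is a header: `{"id", "category", "success_actions",
#' "repeat", "patient", "caregiver"}`; every following line is a turn
#' `{"user": ...}`. With `"repeat": true` the user lines cycle until
#' the turn budget, modelling a user who never gives up.
#'
#' @param path Script path.
#' @return A `conversation_script` list.
#' @export
read_script <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    da_abort(sprintf("script %s: needs a header line and at least one turn", path),
             "dietassist_script_error")
  }
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[i]),
             error = function(e) {
               da_abort(sprintf("script %s line %d: %s", path, i,
                                conditionMessage(e)),
                        "dietassist_script_error")
             })
  }
  header <- parse_line(1)
  for (fld in c("id", "category", "success_actions")) {
    if (is.null(header[[fld]])) {
      da_abort(sprintf("script %s line 1: missing field '%s'", path, fld),
               "dietassist_script_error")
    }
  }
  turns <- map_chr(seq(2L, length(lines)), function(i) {
    x <- parse_line(i)
    if (is.null(x$user)) {
      da_abort(sprintf("script %s line %d: missing 'user'", path, i),
               "dietassist_script_error")
    }
    x$user
  })
  structure(list(id = header$id, category = header$category,
                 success_actions = unlist(header$success_actions),
                 repeat_turns = isTRUE(header[["repeat"]]),
                 patient = header$patient %||% NULL,
                 caregiver = header$caregiver %||% NULL,
                 turns = turns, path = path),
            class = "conversation_script")
}

#' Drive one script through the assistant
#'
#' Feeds the script's user lines to [dm_step()] turn by turn. The
#' dialogue succeeds when an action listed in the script's
#' `success_actions` is produced within `max_turns`; exceeding the
#' threshold without one marks it failed. After the first satisfying
#' response the remaining lines are still replayed (so rejection /
#' follow-up behavior is exercised), but `turns` reports the turn of
#' first success.
#'
#' @param script A [read_script()] result.
#' @param app A [diet_app()].
#' @param patient,caregiver Profiles for the session.
#' @param max_turns Turn threshold (default 20).
#' @return List: `transcript` (tibble), `success`, `turns`, `responses`
#'   (tibble of substantive responses with recomputed correctness).
#' @export
run_script <- function(script, app, patient, caregiver, max_turns = 20) {
  if (length(script$turns) == 0L) {
    da_abort(sprintf("script %s: empty", script$id), "dietassist_script_error")
  }
  session <- dialogue_session(patient, caregiver, id = script$id,
                              max_turns = max_turns)
  transcript <- list()
  responses <- list()
  success <- FALSE
  success_turn <- NA_integer_
  t <- 0L
  repeat {
    if (t >= max_turns) break
    t <- t + 1L
    idx <- if (script$repeat_turns) ((t - 1L) %% length(script$turns)) + 1L else t
    if (idx > length(script$turns)) break
    step <- dm_step(app, session, script$turns[idx])
    transcript[[t]] <- tibble(turn = t, user = script$turns[idx],
                              state = step$state, action = step$action,
                              response = step$response)
    if (step$action %in% c("suitability_verdict", "offer_recipe",
                           "offer_snack", "tip", "explain_food", "history")) {
      responses[[length(responses) + 1L]] <-
        judge_response(app, session, step)
    }
    if (!success && step$action %in% script$success_actions) {
      success <- TRUE
      success_turn <- t
    }
    if (session$done) break
  }
  list(transcript = bind_rows(transcript),
       success = success,
       turns = if (success) success_turn else session$turn_count,
       responses = if (length(responses)) bind_rows(responses) else
         tibble(action = character(), item = character(), correct = logical()))
}

# automated correctness judge: a response is correct when re-deriving it
# from the KB, rules, and profiles reproduces a guideline-consistent
# answer for this patient and caregiver
judge_response <- function(app, session, step) {
  action <- step$action
  item <- step$recommendation %||% NA_character_
  correct <- switch(action,
    offer_recipe = {
      r <- app$kb$recipes[[item]]
      !is.null(r) &&
        nrow(check_meal_constraints(r, session$patient, session$caregiver,
                                    app$kb,
                                    meal = session$slots$meal %||% NULL)) == 0L
    },
    offer_snack = {
      fid <- session$last_offer
      item <- fid %||% NA_character_
      !is.null(fid) &&
        !excluded_by(app$kb, fid, session$patient$allergies) &&
        !excluded_by(app$kb, fid, session$patient$religious_constraints) &&
        !fid %in% session$patient$dislikes &&
        mind_classify(app$kb, fid) != "limit"
    },
    suitability_verdict = {
      fid <- context_get(session, "last_food")
      item <- fid %||% NA_character_
      v <- context_get(session, "last_verdict")
      !is.null(fid) && !is.null(v) &&
        identical(check_food_suitability(fid, session$slots$meal %||% "snack",
                                         session$patient, app$kb,
                                         app$rules)$suitable, v)
    },
    explain_food = {
      fid <- context_get(session, "last_food")
      item <- fid %||% NA_character_
      !is.null(fid) && fid %in% names(app$kb$foods)
    },
    tip = TRUE,
    history = TRUE,
    FALSE
  )
  tibble(action = action, item = item, correct = correct)
}

#' Dialogue success rate
#'
#' The percentage of dialogues that produced a satisfying response
#' within the turn threshold: `100 * n_success / n_total`.
#'
#' @param n_success Number of successful dialogues.
#' @param n_total Number of dialogues (> 0).
#' @return Percentage in `[0, 100]`.
#' @export
success_rate <- function(n_success, n_total) {
  if (!is_count(n_total, 1)) {
    da_abort("success rate undefined: no dialogues", "dietassist_metric_error")
  }
  if (!is_count(n_success) || n_success > n_total) {
    da_abort("n_success must be a count not exceeding n_total",
             "dietassist_metric_error")
  }
  100 * n_success / n_total
}

#' Recommendation correctness rate
#'
#' The percentage of substantive responses judged consistent with the
#' guidelines and profiles: `100 * n_correct / n_responses`.
#'
#' @param n_correct Number of correct responses.
#' @param n_responses Number of responses (> 0).
#' @return Percentage in `[0, 100]`.
#' @export
correctness_rate <- function(n_correct, n_responses) {
  if (!is_count(n_responses, 1)) {
    da_abort("correctness rate undefined: no responses", "dietassist_metric_error")
  }
  if (!is_count(n_correct) || n_correct > n_responses) {
    da_abort("n_correct must be a count not exceeding n_responses",
             "dietassist_metric_error")
  }
  100 * n_correct / n_responses
}

#' Evaluate a directory (or list) of scripts
#'
#' @param scripts Character vector of script paths, or a list of
#'   [read_script()] objects.
#' @param app A [diet_app()].
#' @param profiles Profiles list as returned by [read_profiles()];
#'   scripts name their patient/caregiver, falling back to the first of
#'   each.
#' @param max_turns Turn threshold.
#' @return A `diet_eval` object: list with `outcomes` (per-category
#'   tibble) and `runs` (per-script tibble).
#' @export
evaluate_scripts <- function(scripts, app, profiles, max_turns = 20) {
  if (is.character(scripts)) scripts <- map(sort(scripts), read_script)
  if (length(scripts) == 0L) {
    da_abort("no scripts to evaluate", "dietassist_script_error")
  }
  runs <- map(scripts, function(sc) {
    patient <- profiles$patients[[sc$patient %||% 1L]]
    caregiver <- profiles$caregivers[[sc$caregiver %||% 1L]]
    res <- run_script(sc, app, patient, caregiver, max_turns = max_turns)
    tibble(id = sc$id, category = sc$category, success = res$success,
           turns = res$turns, n_responses = nrow(res$responses),
           n_correct = sum(res$responses$correct))
  })
  runs <- bind_rows(runs)
  outcomes <- dplyr::summarise(
    dplyr::group_by(runs, .data$category),
    n_total = dplyr::n(),
    n_success = sum(.data$success),
    avg_turns = mean(.data$turns),
    n_responses = sum(.data$n_responses),
    n_correct = sum(.data$n_correct),
    .groups = "drop"
  )
  outcomes$success_rate <- 100 * outcomes$n_success / outcomes$n_total
  outcomes$correctness_rate <- ifelse(
    outcomes$n_responses > 0,
    100 * outcomes$n_correct / outcomes$n_responses, NA_real_)
  structure(list(outcomes = outcomes, runs = runs), class = "diet_eval")
}

#' @export
print.diet_eval <- function(x, ...) {
  cat(format_eval_report(x), sep = "\n")
  invisible(x)
}

#' Render the per-category performance report
#'
#' One row per service category: dialogues, average turns per dialogue,
#' dialogue success rate, and recommendation correctness rate.
#'
#' @param x A `diet_eval`.
#' @return Character vector of aligned text lines.
#' @export
format_eval_report <- function(x) {
  o <- x$outcomes
  fmt_pct <- function(v, n) ifelse(is.na(v), "n/a",
                                   sprintf("%.1f%% (%s)", v, n))
  header <- sprintf("%-22s %9s %10s %18s %18s",
                    "category", "dialogues", "avg turns",
                    "success rate", "correctness rate")
  rows <- map_chr(seq_len(nrow(o)), function(i) {
    sprintf("%-22s %9d %10.1f %18s %18s",
            o$category[i], o$n_total[i], o$avg_turns[i],
            fmt_pct(o$success_rate[i],
                    sprintf("%d/%d", o$n_success[i], o$n_total[i])),
            fmt_pct(o$correctness_rate[i],
                    sprintf("%d/%d", o$n_correct[i], o$n_responses[i])))
  })
  c(header, rows)
}

#' Write the evaluation report as CSV
#' @param x A `diet_eval`.
#' @param path Output CSV path.
#' @export
write_eval_report <- function(x, path) {
  utils::write.csv(x$outcomes, path, row.names = FALSE)
  invisible(path)
}

#' @export
tidy.diet_eval <- function(x, ...) {
  as_tibble(x$outcomes)
}

#' @export
glance.diet_eval <- function(x, ...) {
  tibble(
    n_dialogues = sum(x$outcomes$n_total),
    success_rate = 100 * sum(x$outcomes$n_success) / sum(x$outcomes$n_total),
    correctness_rate = 100 * sum(x$outcomes$n_correct) /
      max(sum(x$outcomes$n_responses), 1L),
    avg_turns = mean(x$runs$turns)
  )
}

#' Plot per-category evaluation rates
#'
#' Registered as an `autoplot()` method when ggplot2 is available.
#'
#' @param object A `diet_eval`.
#' @param ... Unused.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_eval <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    da_abort("autoplot needs the ggplot2 package", "dietassist_validation_error")
  }
  o <- object$outcomes
  long <- bind_rows(
    tibble(category = o$category, metric = "success rate", value = o$success_rate),
    tibble(category = o$category, metric = "correctness rate",
           value = o$correctness_rate)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL) +
    ggplot2::theme_minimal()
}
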