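## Discrete-event session engine. All timing is simulated seconds from
## session start; a single seeded RNG per session makes logs replayable.

new_event <- function(t, type, payload = list()) {
  list(t = t, type = type, payload = payload)
}

# mutable event collector
new_log_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$events <- vector("list", 256L)
  env$n <- 0L
  env
}

push_event <- function(env, t, type, payload = list()) {
  env$n <- env$n + 1L
  if (env$n > length(env$events))
    env$events <- c(env$events, vector("list", length(env$events)))
  env$events[[env$n]] <- new_event(t, type, payload)
  invisible(env)
}

collect_events <- function(env) env$events[seq_len(env$n)]

#' Run the adaptive arithmetic task
#'
#' Presents problems, collects responses from a behavior model, classifies
#' them and advances the staircase until the task clock reaches
#' `math_duration_s`. The problem in flight when the clock runs out is
#' truncated without an outcome and excluded from the presented count.
#'
#' @param config a [make_config()] object.
#' @param responder `function(problem, time_limit_s, keypad)` returning
#'   `list(answer = integer or NULL, latency_s = number)`; latency for a
#'   `NULL` answer is ignored (the trial consumes the full time limit).
#' @param t0 session time at which the task starts (seconds).
#' @param max_trials hard cap guarding against degenerate responders.
#' @return list with `events` (task segment of the session log) and `state`
#'   (final `dst_math_state`).
#' @export
run_math_task <- function(config, responder, t0 = 0, max_trials = 10000L) {
  lb <- new_log_builder()
  state <- new_math_state(config)
  t <- t0
  push_event(lb, t, "task_start", list(task = "math"))
  trials <- 0L
  while (t - t0 < config$math_duration_s && trials < max_trials) {
    trials <- trials + 1L
    rescue <- state$rescue_pending
    if (rescue) state$rescue_pending <- FALSE
    problem <- generate_problem(config, rescue = rescue)
    keypad <- next_keypad(state, config)
    swapped <- !identical(keypad, 1:10)
    if (state$swap_remaining > 0L)
      state$swap_remaining <- state$swap_remaining - 1L
    if (swapped) push_event(lb, t, "keypad_set", list(layout = keypad))
    push_event(lb, t, "problem_presented",
               list(op = problem$op, a = problem$a, b = problem$b,
                    solution = problem$solution, rescue = rescue,
                    time_limit_s = state$time_limit_s, swapped = swapped))
    resp <- responder(problem, state$time_limit_s, keypad)
    dt <- if (is.null(resp$answer)) state$time_limit_s
          else min(resp$latency_s, state$time_limit_s)
    if (t + dt - t0 > config$math_duration_s) {
      # task clock expires mid-trial: truncate without an outcome
      t <- t0 + config$math_duration_s
      break
    }
    t <- t + dt
    outcome <- classify_response(problem, resp$answer, resp$latency_s,
                                 state$time_limit_s)
    limit_before <- state$time_limit_s
    state <- apply_outcome(state, outcome, config)
    push_event(lb, t, "response",
               list(kind = outcome$kind, latency_s = outcome$latency_s,
                    answer = if (is.null(resp$answer)) NULL else resp$answer))
    push_event(lb, t, "feedback",
               list(kind = outcome$kind, percent_correct = percent_correct(state)))
    if (state$time_limit_s != limit_before)
      push_event(lb, t, "adaptation",
                 list(time_limit_s = state$time_limit_s,
                      direction = if (state$time_limit_s < limit_before) "harder" else "easier"))
    if (state$rescue_pending)
      push_event(lb, t, "rescue_triggered", list(n_presented = state$n_presented))
  }
  t_end <- t
  push_event(lb, t_end, "task_end",
             list(task = "math",
                  percent_correct = percent_correct(state),
                  comparison_pct = config$comparison_pct,
                  n_presented = state$n_presented,
                  n_correct = state$n_correct))
  list(events = collect_events(lb), state = state, t_end = t_end)
}

#' Run the free-speech task
#'
#' Schedules the configured scenarios (preparation then presentation
#' windows) and emits one silence reminder per maximal silent gap at least
#' `silence_reminder_s` long during each presentation window.
#'
#' @param config a [make_config()] object.
#' @param speaker `function(scenario_index, present_s)` returning a
#'   two-column matrix (or `NULL`) of silent gaps, columns `start` and
#'   `length`, in seconds within the presentation window.
#' @param scenarios data frame with columns `id`, `prompt` (one row per
#'   scenario); defaults to the bundled scenario set for the condition.
#' @param t0 session time at which the task starts (seconds).
#' @return list with `events` and `t_end`.
#' @export
run_speech_task <- function(config, speaker, scenarios = NULL, t0 = 0) {
  if (is.null(scenarios)) scenarios <- speech_scenarios(config$condition)
  stopifnot(nrow(scenarios) >= config$n_speech_scenarios)
  lb <- new_log_builder()
  t <- t0
  push_event(lb, t, "task_start", list(task = "speech"))
  for (i in seq_len(config$n_speech_scenarios)) {
    push_event(lb, t, "scenario_start",
               list(id = scenarios$id[i], prompt = scenarios$prompt[i],
                    prep_s = config$prep_s, present_s = config$present_s))
    t_present <- t + config$prep_s
    gaps <- speaker(i, config$present_s)
    if (!is.null(gaps) && nrow(gaps) > 0) {
      for (g in seq_len(nrow(gaps))) {
        if (gaps[g, "length"] >= config$silence_reminder_s) {
          push_event(lb, t_present + gaps[g, "start"] + config$silence_reminder_s,
                     "silence_reminder", list(scenario = i))
        }
      }
    }
    t <- t_present + config$present_s
  }
  push_event(lb, t, "task_end", list(task = "speech"))
  list(events = collect_events(lb), t_end = t)
}

# nominal reading/answering durations for non-task stages (seconds)
.stage_durations <- c(framing = 60, panas = 40, vas = 25, elements = 60)

#' Simulate one full session
#'
#' Runs the complete protocol for one simulated participant: framing,
#' baseline questionnaires (I-PANAS-SF + 4 VAS scales), arithmetic task,
#' intermediate VAS, speech task, post questionnaires and the element-rating
#' questionnaire, with a dropout checkpoint before every stage. Completed
#' sessions therefore contain exactly 2 PANAS and 3 VAS questionnaire
#' events.
#'
#' @param config a [make_config()] object.
#' @param participant a [make_participant()] bundle (responder, speaker,
#'   affect targets, dropout hazards, pace, flags).
#' @param seed integer seed; recorded in the log metadata and set at session
#'   start so that identical inputs replay to an identical log.
#' @param participant_id identifier stored in the log metadata.
#' @return A `dst_session_log`: `list(meta = ..., events = ...)`.
#' @export
run_session <- function(config, participant, seed, participant_id = "p1") {
  validate_config(config)
  set.seed(as.integer(seed))
  lb <- new_log_builder()
  t <- 0
  pace <- participant$pace %||% 1
  hz <- participant$dropout
  dropped <- FALSE
  checkpoint <- function(stage) {
    h <- if (stage %in% names(hz)) hz[[stage]] else 0
    if (stats::runif(1) < h) {
      push_event(lb, t, "dropout", list(stage = stage))
      TRUE
    } else FALSE
  }

  push_event(lb, t, "session_start", list())
  push_event(lb, t, "framing_shown",
             list(comparison_pct = config$comparison_pct,
                  condition = config$condition))
  t <- t + .stage_durations[["framing"]] * pace

  affect <- participant$affect  # per-timepoint questionnaire targets
  emit_panas <- function(timepoint) {
    items <- sample_panas_items(affect$panas[[timepoint]])
    push_event(lb, t, "questionnaire",
               list(instrument = "panas", timepoint = timepoint,
                    items = as.list(items)))
    t <<- t + .stage_durations[["panas"]] * pace
  }
  emit_vas <- function(timepoint) {
    push_event(lb, t, "questionnaire",
               list(instrument = "vas", timepoint = timepoint,
                    values = as.list(affect$vas[[timepoint]])))
    t <<- t + .stage_durations[["vas"]] * pace
  }

  repeat {  # single-pass staged flow; `repeat` only to allow early break
    if (checkpoint("intro")) { dropped <- TRUE; break }
    emit_panas("baseline")
    emit_vas("baseline")
    if (checkpoint("math")) { dropped <- TRUE; break }
    math <- run_math_task(config, participant$responder, t0 = t)
    for (e in math$events) push_event(lb, e$t, e$type, e$payload)
    t <- math$t_end
    if (checkpoint("intermediate")) { dropped <- TRUE; break }
    emit_vas("intermediate")
    if (checkpoint("speech")) { dropped <- TRUE; break }
    speech <- run_speech_task(config, participant$speaker, t0 = t)
    for (e in speech$events) push_event(lb, e$t, e$type, e$payload)
    t <- speech$t_end
    if (checkpoint("post")) { dropped <- TRUE; break }
    emit_panas("post")
    emit_vas("post")
    push_event(lb, t, "questionnaire",
               list(instrument = "elements", timepoint = "post",
                    values = as.list(affect$elements)))
    t <- t + .stage_durations[["elements"]] * pace
    push_event(lb, t, "session_end", list(duration_s = t))
    break
  }

  log <- list(
    meta = list(schema_version = "1",
                participant_id = participant_id,
                condition = config$condition,
                seed = as.integer(seed),
                prior_knowledge = isTRUE(participant$prior_knowledge),
                usability_issue = isTRUE(participant$usability_issue),
                config = unclass(config)),
    events = collect_events(lb)
  )
  class(log) <- "dst_session_log"
  log
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dst_session_log <- function(x, ...) {
  n <- length(x$events)
  last <- if (n) x$events[[n]]$type else "(empty)"
  cat(sprintf("<dst_session_log: %s, participant %s, seed %d, %d events, ends with %s>\n",
              x$meta$condition, x$meta$participant_id, x$meta$seed, n, last))
  invisible(x)
}

#' Bundled speech scenarios
#'
#' Three scenario prompts per condition: socially uncomfortable
#' interview-style questions for the stress condition, neutral everyday
#' topics for the control condition. The bundled texts are representative
#' stand-ins written for this package, not the deployed study wording.
#'
#' @param condition `"stress"` or `"control"`.
#' @return data frame with columns `condition`, `id`, `prompt`.
#' @export
speech_scenarios <- function(condition = c("stress", "control")) {
  condition <- match.arg(condition)
  path <- system.file("extdata", "speech_scenarios.csv", package = "dstsim")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab[tab$condition == condition, , drop = FALSE]
}
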