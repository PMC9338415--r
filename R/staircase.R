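## Transformed up-down staircase controlling the arithmetic time limit.
## Equal up/down run lengths (stress: 3/3) balance long-run accuracy at 50%;
## the control condition's 4-correct/1-wrong rule pushes accuracy far higher.

#' Fresh staircase state for a math task
#'
#' @param config a [make_config()] object.
#' @return A list of class `dst_math_state`: `time_limit_s`,
#'   `consecutive_correct`, `consecutive_wrong_or_timeout`,
#'   `consecutive_no_input`, `swap_remaining`, `rescue_pending`, `n_correct`,
#'   `n_presented`, `elapsed_s`.
#' @export
new_math_state <- function(config) {
  st <- list(
    time_limit_s = config$initial_time_limit_s,
    consecutive_correct = 0L,
    consecutive_wrong_or_timeout = 0L,
    consecutive_no_input = 0L,
    swap_remaining = 0L,
    rescue_pending = FALSE,
    n_correct = 0L,
    n_presented = 0L,
    elapsed_s = 0
  )
  class(st) <- "dst_math_state"
  st
}

#' Advance the staircase after one classified trial
#'
#' Updates streak counters and the adaptive time limit. A run of
#' `harder_streak` correct answers shortens the limit by the adaptation
#' fraction and (stress condition) opens a keypad-swap window of
#' `swap_task_count` tasks; a run of `easier_streak` wrong-or-timeout trials
#' lengthens it. A run of `rescue_no_input_streak` trials with no input at
#' all marks a rescue: the next generated problem is an easy addition. The
#' triggering streak counter resets to zero when its adjustment fires, and
#' the limit is clamped to `time_limit_bounds`.
#'
#' @param state a `dst_math_state`.
#' @param outcome a `dst_outcome` from [classify_response()].
#' @param config a [make_config()] object.
#' @return The updated state; `$events` attribute-free, but the fields
#'   `rescue_pending` and `swap_remaining` reflect any triggered rule.
#' @export
apply_outcome <- function(state, outcome, config) {
  state$n_presented <- state$n_presented + 1L
  if (outcome$kind == "correct") {
    state$n_correct <- state$n_correct + 1L
    state$consecutive_correct <- state$consecutive_correct + 1L
    state$consecutive_wrong_or_timeout <- 0L
    state$consecutive_no_input <- 0L
  } else if (outcome$kind == "wrong") {
    state$consecutive_wrong_or_timeout <- state$consecutive_wrong_or_timeout + 1L
    state$consecutive_correct <- 0L
    state$consecutive_no_input <- 0L  # a keypress happened
  } else {  # timeout_no_input
    state$consecutive_wrong_or_timeout <- state$consecutive_wrong_or_timeout + 1L
    state$consecutive_no_input <- state$consecutive_no_input + 1L
    state$consecutive_correct <- 0L
  }

  if (state$consecutive_correct >= config$harder_streak) {
    state$time_limit_s <- state$time_limit_s * (1 - config$adapt_factor)
    state$consecutive_correct <- 0L
    if (config$condition == "stress")
      state$swap_remaining <- config$swap_task_count
  }
  if (state$consecutive_wrong_or_timeout >= config$easier_streak) {
    state$time_limit_s <- state$time_limit_s * (1 + config$adapt_factor)
    state$consecutive_wrong_or_timeout <- 0L
  }
  if (config$rescue_enabled &&
      state$consecutive_no_input >= config$rescue_no_input_streak) {
    state$rescue_pending <- TRUE
    state$consecutive_no_input <- 0L
  }
  state$time_limit_s <- min(max(state$time_limit_s, config$time_limit_bounds[1]),
                            config$time_limit_bounds[2])
  state
}

#' Live percentage of correct answers
#'
#' The running score shown to the participant alongside the fabricated
#' comparison-group average. Timeouts count in the denominator; before the
#' first task the display convention is 0.
#'
#' @param state a `dst_math_state`.
#' @return percentage in \[0, 100\].
#' @export
percent_correct <- function(state) {
  if (state$n_presented == 0L) return(0)
  100 * state$n_correct / state$n_presented
}

#' Run the staircase for a fixed number of trials
#'
#' Analysis helper that iterates generate-respond-classify-apply for exactly
#' `n_trials` trials with no task clock, for studying the staircase's
#' long-run operating point. The responder is a function of the current time
#' limit returning the probability of a correct answer on that trial.
#'
#' @param config a [make_config()] object.
#' @param p_correct function(limit_s) -> probability of a correct response.
#' @param n_trials number of trials.
#' @param p_no_input probability that an incorrect trial is silent (no
#'   keypress) rather than a wrong answer.
#' @return list with `accuracy` (overall proportion correct), `limits`
#'   (per-trial time limit) and `state` (final `dst_math_state`).
#' @export
simulate_staircase <- function(config, p_correct, n_trials, p_no_input = 0.5) {
  state <- new_math_state(config)
  limits <- numeric(n_trials)
  correct <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    limits[i] <- state$time_limit_s
    ok <- stats::runif(1) < p_correct(state$time_limit_s)
    kind <- if (ok) "correct"
            else if (stats::runif(1) < p_no_input) "timeout_no_input" else "wrong"
    out <- structure(list(kind = kind,
                          latency_s = if (kind == "timeout_no_input") NA_real_ else 0),
                     class = "dst_outcome")
    state <- apply_outcome(state, out, config)
    state$rescue_pending <- FALSE  # no problem generation in this helper
    correct[i] <- ok
  }
  list(accuracy = mean(correct), limits = limits, state = state)
}
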