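## Behavior models for simulated participants: arithmetic skill (solve-time
## and accuracy under time pressure), speech silence gaps, and stage-wise
## dropout hazards.

#' Arithmetic skill profile
#'
#' Parameterizes how a simulated participant responds to arithmetic
#' problems. Solve times are log-normal per operation; the probability of a
#' correct answer is the base accuracy attenuated by time pressure through a
#' logistic link on the log time-limit/solve-time ratio; a permuted keypad
#' adds motor time.
#'
#' @param solve_median_s named vector of median solve times (seconds) per
#'   operation (`add`, `sub`, `mul`, `div`).
#' @param solve_log_sd log-scale SD of solve times.
#' @param base_accuracy probability of a correct answer given ample time.
#' @param pressure_slope slope of the logistic attenuation in
#'   `log(limit / solve_time)`; larger is more deterministic.
#' @param swap_penalty_s motor seconds added while the keypad is permuted.
#' @param p_no_input per-trial probability of giving no input at all.
#' @param silence_gap_rate expected silent gaps per minute of speech.
#' @param silence_gap_mean_s mean length (seconds) of a silent gap
#'   (exponential).
#' @return object of class `dst_skill`.
#' @export
skill_profile <- function(solve_median_s = c(add = 1.6, sub = 2.0, mul = 2.8, div = 2.8),
                          solve_log_sd = 0.35,
                          base_accuracy = 0.95,
                          pressure_slope = 3,
                          swap_penalty_s = 0.8,
                          p_no_input = 0.02,
                          silence_gap_rate = 2,
                          silence_gap_mean_s = 0.8) {
  stopifnot(all(solve_median_s > 0), solve_log_sd >= 0,
            base_accuracy >= 0, base_accuracy <= 1,
            p_no_input >= 0, p_no_input <= 1,
            swap_penalty_s >= 0, silence_gap_rate >= 0, silence_gap_mean_s > 0)
  structure(list(solve_median_s = solve_median_s, solve_log_sd = solve_log_sd,
                 base_accuracy = base_accuracy, pressure_slope = pressure_slope,
                 swap_penalty_s = swap_penalty_s, p_no_input = p_no_input,
                 silence_gap_rate = silence_gap_rate,
                 silence_gap_mean_s = silence_gap_mean_s),
            class = "dst_skill")
}

#' Respond to one arithmetic problem
#'
#' Draws a solve time from the operation's log-normal distribution (plus the
#' swap penalty when the keypad is permuted). With probability `p_no_input`
#' the participant stays silent. If the solve time exceeds the limit the
#' trial times out; otherwise the typed answer equals the solution with
#' probability `base_accuracy * plogis(pressure_slope * log(limit / solve_time))`,
#' and is a near-miss digit error otherwise.
#'
#' @param skill a [skill_profile()].
#' @param problem a `dst_problem`.
#' @param time_limit_s current staircase limit.
#' @param keypad keypad layout from [next_keypad()].
#' @return `list(answer = integer or NULL, latency_s = number)`.
#' @export
respond_math <- function(skill, problem, time_limit_s, keypad = 1:10) {
  if (stats::runif(1) < skill$p_no_input)
    return(list(answer = NULL, latency_s = time_limit_s))
  med <- skill$solve_median_s[[problem$op]]
  solve_t <- stats::rlnorm(1, meanlog = log(med), sdlog = skill$solve_log_sd)
  if (!identical(keypad, 1:10)) solve_t <- solve_t + skill$swap_penalty_s
  if (solve_t >= time_limit_s)
    return(list(answer = NULL, latency_s = time_limit_s))
  p_ok <- skill$base_accuracy *
    stats::plogis(skill$pressure_slope * log(time_limit_s / solve_t))
  if (stats::runif(1) < p_ok) {
    list(answer = problem$solution, latency_s = solve_t)
  } else {
    off <- sample(c(-10L, -1L, 1L, 10L), 1L)
    wrong <- problem$solution + off
    if (wrong == problem$solution || wrong < 0L) wrong <- problem$solution + 1L
    list(answer = wrong, latency_s = solve_t)
  }
}

# speaker closure: Poisson-count exponential-length silent gaps per window
make_speaker <- function(skill) {
  function(scenario_index, present_s) {
    n <- stats::rpois(1, skill$silence_gap_rate * present_s / 60)
    if (n == 0L) return(NULL)
    start <- sort(stats::runif(n, 0, present_s))
    len <- stats::rexp(n, rate = 1 / skill$silence_gap_mean_s)
    len <- pmin(len, present_s - start)
    cbind(start = start, length = len)
  }
}

#' Stage-wise dropout hazards
#'
#' Per-stage probabilities of quitting before each protocol stage (`intro`,
#' `math`, `intermediate`, `speech`, `post`). `default_dropout()` returns
#' the default hazard set for a condition: the later-stage hazards are fixed
#' at values reflecting the observed dropout pattern (most attrition in the
#' stress arm happens before the arithmetic task begins), and the intro
#' hazard is solved so that the product of stage survival probabilities
#' equals the observed completion fraction (112/300 for the stress arm,
#' 206/247 for the control arm).
#'
#' @param condition `"stress"` or `"control"`.
#' @return named numeric vector of 5 hazards in \[0, 1\].
#' @export
default_dropout <- function(condition = c("stress", "control")) {
  condition <- match.arg(condition)
  if (condition == "stress") {
    target <- 112 / 300
    later <- c(math = 0.15, intermediate = 0.08, speech = 0.15, post = 0.02)
  } else {
    target <- 206 / 247
    later <- c(math = 0.04, intermediate = 0.02, speech = 0.03, post = 0.005)
  }
  intro <- 1 - target / prod(1 - later)
  stopifnot(intro >= 0, intro < 1)
  c(intro = intro, later)
}

#' Bundle a simulated participant
#'
#' Combines the behavior models the session engine consumes: an arithmetic
#' responder, a speech model, per-timepoint affect targets, dropout hazards,
#' a pace multiplier for non-task stages and the exclusion-relevant flags.
#'
#' @param skill a [skill_profile()].
#' @param affect_targets output of [draw_affect()] (with `elements` filled
#'   in if element ratings are wanted).
#' @param dropout named hazard vector, see [default_dropout()]; use
#'   `rep(0, 5)`-style zero hazards for guaranteed completers.
#' @param pace multiplier on nominal reading/answering durations.
#' @param prior_knowledge,usability_issue exclusion indicator flags.
#' @return list consumed by [run_session()].
#' @export
make_participant <- function(skill = skill_profile(),
                             affect_targets,
                             dropout = c(intro = 0, math = 0, intermediate = 0,
                                         speech = 0, post = 0),
                             pace = 1,
                             prior_knowledge = FALSE,
                             usability_issue = FALSE) {
  list(responder = function(problem, time_limit_s, keypad)
         respond_math(skill, problem, time_limit_s, keypad),
       speaker = make_speaker(skill),
       affect = affect_targets,
       dropout = dropout,
       pace = pace,
       prior_knowledge = prior_knowledge,
       usability_issue = usability_issue)
}
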