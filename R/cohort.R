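## Cohort-level simulation: many seeded sessions per arm plus the long
## questionnaire table the statistical pipeline consumes.

#' Specification of a synthetic two-arm cohort
#'
#' @param n_stress,n_control arm sizes (numbers of participants who *start*
#'   each condition; completers are fewer when dropout hazards are nonzero).
#' @param seed master seed; per-participant session seeds are derived from it.
#' @param affect output of [affect_defaults()] or a same-shaped list with
#'   `stress`/`control` [affect_profile()]s.
#' @param skill a [skill_profile()] shared by all participants.
#' @param dropout `"default"` for [default_dropout()] per condition, `"none"`
#'   for guaranteed completers, or a named list with `stress`/`control`
#'   hazard vectors.
#' @param prior_knowledge_prob,usability_prob per-participant probabilities
#'   of the corresponding exclusion flags.
#' @return object of class `dst_cohort_spec`.
#' @export
cohort_spec <- function(n_stress, n_control, seed,
                        affect = affect_defaults("table2_default"),
                        skill = skill_profile(),
                        dropout = "default",
                        prior_knowledge_prob = 0.024,
                        usability_prob = 0.035) {
  stopifnot(n_stress >= 0, n_control >= 0)
  if (identical(dropout, "default"))
    dropout <- list(stress = default_dropout("stress"),
                    control = default_dropout("control"))
  else if (identical(dropout, "none"))
    dropout <- list(stress = c(intro = 0, math = 0, intermediate = 0,
                               speech = 0, post = 0),
                    control = c(intro = 0, math = 0, intermediate = 0,
                                speech = 0, post = 0))
  structure(list(n_stress = as.integer(n_stress),
                 n_control = as.integer(n_control),
                 seed = as.integer(seed),
                 affect = affect, skill = skill, dropout = dropout,
                 prior_knowledge_prob = prior_knowledge_prob,
                 usability_prob = usability_prob),
            class = "dst_cohort_spec")
}

#' Simulate a cohort of sessions
#'
#' Runs one full seeded session per participant in each arm and assembles
#' the completers' scored questionnaire responses into a long table
#' (`participant_id`, `group`, `time`, `measure`, `value`) with PANAS
#' subscales at 2 timepoints and the 4 VAS scales at 3 timepoints.
#'
#' @param spec a [cohort_spec()].
#' @param completers_only keep only participants whose log contains a
#'   `session_end` event in the questionnaire table (the logs of dropouts
#'   are still returned).
#' @return list with `logs` (list of `dst_session_log`) and `questionnaires`
#'   (long data frame).
#' @export
simulate_cohort <- function(spec, completers_only = TRUE) {
  stopifnot(inherits(spec, "dst_cohort_spec"))
  set.seed(spec$seed)
  arms <- c(rep("stress", spec$n_stress), rep("control", spec$n_control))
  n <- length(arms)
  if (n == 0L)
    return(list(logs = list(), questionnaires = empty_questionnaire_table()))
  session_seeds <- sample.int(.Machine$integer.max, n)
  configs <- list(stress = make_config("stress"), control = make_config("control"))
  logs <- vector("list", n)
  for (i in seq_len(n)) {
    arm <- arms[i]
    targets <- draw_affect(spec$affect[[arm]])
    targets$elements <- sample_element_ratings(arm)
    p <- make_participant(
      skill = spec$skill,
      affect_targets = targets,
      dropout = spec$dropout[[arm]],
      pace = stats::rlnorm(1, meanlog = 0, sdlog = 0.15),
      prior_knowledge = stats::runif(1) < spec$prior_knowledge_prob,
      usability_issue = stats::runif(1) < spec$usability_prob)
    logs[[i]] <- run_session(configs[[arm]], p, seed = session_seeds[i],
                             participant_id = sprintf("%s_%03d", arm, i))
  }
  list(logs = logs,
       questionnaires = questionnaire_table(logs, completers_only = completers_only))
}

empty_questionnaire_table <- function() {
  data.frame(participant_id = character(), group = character(),
             time = character(), measure = character(), value = numeric(),
             stringsAsFactors = FALSE)
}

#' Extract the scored questionnaire long table from session logs
#'
#' Scores every PANAS questionnaire event with [score_panas()] and carries
#' VAS values through unchanged.
#'
#' @param logs list of `dst_session_log` objects.
#' @param completers_only drop participants without a `session_end` event.
#' @return long data frame (`participant_id`, `group`, `time`, `measure`,
#'   `value`).
#' @export
questionnaire_table <- function(logs, completers_only = TRUE) {
  rows <- list()
  for (log in logs) {
    if (completers_only && !session_complete(log)) next
    pid <- log$meta$participant_id
    grp <- log$meta$condition
    for (e in log$events) {
      if (e$type != "questionnaire") next
      pl <- e$payload
      if (pl$instrument == "panas") {
        sc <- score_panas(unlist(pl$items))
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, group = grp, time = pl$timepoint,
          measure = c("panas_na", "panas_pa"), value = c(sc$na, sc$pa),
          stringsAsFactors = FALSE)
      } else if (pl$instrument == "vas") {
        v <- unlist(pl$values)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, group = grp, time = pl$timepoint,
          measure = paste0("vas_", names(v)), value = unname(v),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_questionnaire_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract element ratings from session logs
#'
#' @param logs list of `dst_session_log` objects.
#' @param completers_only drop participants without a `session_end` event.
#' @return long data frame (`participant_id`, `group`, `element`, `value`);
#'   condition-inapplicable elements are omitted.
#' @export
element_table <- function(logs, completers_only = TRUE) {
  rows <- list()
  for (log in logs) {
    if (completers_only && !session_complete(log)) next
    for (e in log$events) {
      if (e$type != "questionnaire" || e$payload$instrument != "elements") next
      v <- unlist(e$payload$values)
      keep <- !is.na(v)
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = log$meta$participant_id,
        group = log$meta$condition,
        element = names(v)[keep], value = unname(v[keep]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(participant_id = character(), group = character(),
                      element = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

session_complete <- function(log) {
  any(vapply(log$events, function(e) e$type == "session_end", logical(1)))
}

#' Fast questionnaire-only cohort draw
#'
#' Generates the scored long questionnaire table directly from the affect
#' model (including itemization and instrument scoring) without running the
#' protocol engine or dropout process. The engine does not feed back into
#' the questionnaires, so this is distributionally identical to the
#' completers' table from [simulate_cohort()] with zero dropout; it is the
#' workhorse for replicated statistical calibration studies.
#'
#' @param n_stress,n_control numbers of completers per arm.
#' @param affect as in [cohort_spec()].
#' @param seed integer seed.
#' @param measures optional subset of measures to generate, e.g.
#'   `"panas_na"`.
#' @return long data frame (`participant_id`, `group`, `time`, `measure`,
#'   `value`).
#' @export
simulate_questionnaires <- function(n_stress, n_control, seed,
                                    affect = affect_defaults("table2_default"),
                                    measures = NULL) {
  set.seed(as.integer(seed))
  arms <- c(rep("stress", n_stress), rep("control", n_control))
  rows <- vector("list", length(arms))
  for (i in seq_along(arms)) {
    arm <- arms[i]
    prof <- spec_subset(affect[[arm]], measures)
    tg <- draw_affect(prof)
    pid <- sprintf("%s_%03d", arm, i)
    part <- list()
    if (!is.null(tg$panas$baseline$na) || !is.null(tg$panas$baseline$pa)) {
      for (tp in names(tg$panas)) {
        st <- tg$panas[[tp]]
        if (is.null(st$na) || is.null(st$pa)) {
          # single-subscale profile: skip itemization, use target directly
          for (sub in c("na", "pa")) if (!is.null(st[[sub]]))
            part[[length(part) + 1L]] <- data.frame(
              participant_id = pid, group = arm, time = tp,
              measure = paste0("panas_", sub), value = st[[sub]],
              stringsAsFactors = FALSE)
        } else {
          sc <- score_panas(sample_panas_items(st))
          part[[length(part) + 1L]] <- data.frame(
            participant_id = pid, group = arm, time = tp,
            measure = c("panas_na", "panas_pa"), value = c(sc$na, sc$pa),
            stringsAsFactors = FALSE)
        }
      }
    }
    for (tp in names(tg$vas)) {
      v <- tg$vas[[tp]]
      if (!length(v)) next
      part[[length(part) + 1L]] <- data.frame(
        participant_id = pid, group = arm, time = tp,
        measure = paste0("vas_", names(v)), value = unname(v),
        stringsAsFactors = FALSE)
    }
    rows[[i]] <- if (length(part)) do.call(rbind, part) else NULL
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_questionnaire_table())
  rownames(out) <- NULL
  out
}

spec_subset <- function(profile, measures) {
  if (is.null(measures)) return(profile)
  structure(profile[intersect(names(profile), measures)],
            class = "dst_affect_profile")
}

#' Exclusion flags for one session log
#'
#' Mirrors the study's participant filters: incomplete sessions (no session
#' end), self-reported prior knowledge of the framing, self-reported
#' usability issues, and unrealistic total procedure duration. The duration
#' window is configurable; no threshold is implied by the protocol itself.
#'
#' @param log a `dst_session_log`.
#' @param min_duration_s,max_duration_s plausible completed-session duration
#'   window (seconds).
#' @return named logical vector: `incomplete`, `prior_knowledge`,
#'   `usability_issue`, `duration_outlier`, `excluded` (any of the above).
#' @export
exclusion_flags <- function(log, min_duration_s = 120, max_duration_s = 1800) {
  complete <- session_complete(log)
  dur_flag <- FALSE
  if (complete) {
    dur <- log$events[[length(log$events)]]$t
    dur_flag <- dur < min_duration_s || dur > max_duration_s
  }
  flags <- c(incomplete = !complete,
             prior_knowledge = isTRUE(log$meta$prior_knowledge),
             usability_issue = isTRUE(log$meta$usability_issue),
             duration_outlier = dur_flag)
  c(flags, excluded = any(flags))
}

#' Exclusion bookkeeping from category counts
#'
#' Applies the study's exclusion arithmetic to started/excluded counts
#' (categories disjoint) and returns the analyzable sample size.
#'
#' @param n_started participants who started a session.
#' @param incomplete,prior_knowledge,usability_issue,duration_outlier counts
#'   excluded per category.
#' @return list with `n_retained` and `n_excluded`.
#' @examples
#' exclusion_summary(547, 229, 13, 19, 2)$n_retained  # 284
#' @export
exclusion_summary <- function(n_started, incomplete, prior_knowledge,
                              usability_issue, duration_outlier) {
  n_exc <- incomplete + prior_knowledge + usability_issue + duration_outlier
  stopifnot(n_exc <= n_started)
  list(n_retained = n_started - n_exc, n_excluded = n_exc)
}

#' Completion percentage
#'
#' @param n_completed,n_started counts.
#' @return percentage (0-100).
#' @examples
#' completion_fraction(206, 247)  # 83.40081
#' @export
completion_fraction <- function(n_completed, n_started) {
  stopifnot(n_started > 0, n_completed >= 0, n_completed <= n_started)
  100 * n_completed / n_started
}
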