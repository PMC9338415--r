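# Deterministic responder/speaker models and small closed-form oracles used
# across the test files.

always_correct <- function(latency = 1e-6) {
  function(problem, time_limit_s, keypad) {
    list(answer = problem$solution, latency_s = latency)
  }
}

always_silent <- function() {
  function(problem, time_limit_s, keypad) list(answer = NULL, latency_s = time_limit_s)
}

always_wrong <- function(latency = 0.5) {
  function(problem, time_limit_s, keypad) {
    list(answer = problem$solution + 1L, latency_s = latency)
  }
}

silent_speaker <- function() function(i, present_s) NULL

gap_speaker <- function(gaps) function(i, present_s) gaps

# logistic accuracy responder for staircase operating-point studies
logistic_p <- function(tau = 2, slope = 4) function(limit) stats::plogis(slope * log(limit / tau))

event_types <- function(log_or_events) {
  ev <- if (inherits(log_or_events, "dst_session_log")) log_or_events$events else log_or_events
  vapply(ev, function(e) e$type, character(1))
}

# closed-form Welch t oracle (independent of stats::t.test)
welch_oracle <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# closed-form paired t oracle
paired_oracle <- function(pre, post) {
  ch <- post - pre
  n <- length(ch)
  t <- mean(ch) / (sd(ch) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# completer participant with fixed affect targets for session-structure tests
fixture_participant <- function(condition = "stress", seed = 501,
                                dropout = c(intro = 0, math = 0, intermediate = 0,
                                            speech = 0, post = 0), ...) {
  prof <- affect_defaults("table2_default")[[condition]]
  set.seed(seed)
  tg <- draw_affect(prof)
  tg$elements <- sample_element_ratings(condition)
  make_participant(affect_targets = tg, dropout = dropout, ...)
}

# long table from per-group wide score matrices (columns = time levels)
long_from_wide <- function(mats, measure = "m") {
  rows <- lapply(names(mats), function(g) {
    m <- mats[[g]]
    data.frame(participant_id = rep(paste0(g, seq_len(nrow(m))), ncol(m)),
               group = g,
               time = rep(colnames(m), each = nrow(m)),
               measure = measure,
               value = as.vector(m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
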