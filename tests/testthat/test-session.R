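test_that("an instant always-correct responder tightens the limit geometrically", {
  cfg <- make_config("stress", math_duration_s = 1e6,
                     time_limit_bounds = c(1e-9, 30))
  set.seed(5)
  res <- run_math_task(cfg, always_correct(), max_trials = 3 * 7)
  expect_identical(res$state$n_presented, 21L)
  expect_identical(res$state$n_correct, 21L)
  expect_equal(res$state$time_limit_s, 3 * 0.9^7, tolerance = 1e-12)
})

test_that("a silent stress participant triggers a rescue every 5 presented tasks", {
  cfg <- make_config("stress", math_duration_s = 1e4)
  set.seed(6)
  res <- run_math_task(cfg, always_silent(), max_trials = 12)
  types <- event_types(res$events)
  rescue_idx <- which(types == "rescue_triggered")
  presented_at <- vapply(rescue_idx,
                         function(i) res$events[[i]]$payload$n_presented, numeric(1))
  expect_identical(presented_at[1:2], c(5, 10))
  # the trial after a rescue is an easy addition
  probs <- res$events[types == "problem_presented"]
  expect_true(probs[[6]]$payload$rescue)
  expect_identical(probs[[6]]$payload$op, "add")
  expect_false(any(vapply(probs[1:5], function(e) e$payload$rescue, logical(1))))
})

test_that("the math task stops at the 90-second clock and truncates the trial in flight", {
  cfg <- make_config("stress")
  set.seed(8)
  res <- run_math_task(cfg, function(p, l, k) list(answer = p$solution, latency_s = 2.0))
  expect_lte(res$t_end, cfg$math_duration_s)
  types <- event_types(res$events)
  n_resp <- sum(types %in% "response")
  expect_identical(res$state$n_presented, as.integer(n_resp))  # truncated trial uncounted
  final <- res$events[[length(res$events)]]
  expect_identical(final$type, "task_end")
  expect_equal(final$payload$comparison_pct, 75)
  expect_equal(final$payload$percent_correct, percent_correct(res$state))
  # silent participant: 90 s at 3 s per trial, easing every 3 timeouts
  set.seed(9)
  silent <- run_math_task(cfg, always_silent())
  expect_lte(max(vapply(silent$events, `[[`, numeric(1), "t")), 90)
})

test_that("no swap, rescue or comparison machinery appears in the control condition", {
  cfg <- make_config("control", math_duration_s = 600)
  set.seed(10)
  res <- run_math_task(cfg, always_silent(), max_trials = 40)
  types <- event_types(res$events)
  expect_false(any(types %in% c("keypad_set", "rescue_triggered")))
  expect_identical(res$state$swap_remaining, 0L)
  expect_true(is.na(res$events[[length(res$events)]]$payload$comparison_pct))
  # even a fast perfect responder never sees a swapped keypad in control
  set.seed(11)
  res2 <- run_math_task(make_config("control", math_duration_s = 1e5),
                        always_correct(), max_trials = 40)
  expect_false(any(event_types(res2$events) == "keypad_set"))
})

test_that("speech task schedules 3 scenarios and one reminder per long gap", {
  cfg <- make_config("stress")
  res <- run_speech_task(cfg, silent_speaker(), t0 = 100)
  expect_equal(res$t_end - 100, 3 * (10 + 20))
  types <- event_types(res$events)
  expect_identical(sum(types == "scenario_start"), 3L)
  expect_identical(sum(types == "silence_reminder"), 0L)

  one_gap <- gap_speaker(cbind(start = 5, length = 1.2))
  res1 <- run_speech_task(cfg, one_gap)
  expect_identical(sum(event_types(res1$events) == "silence_reminder"), 3L)  # one per scenario
  # a 5 s gap is still a single maximal gap -> a single reminder
  res5 <- run_speech_task(cfg, function(i, p) if (i == 1) cbind(start = 2, length = 5) else NULL)
  expect_identical(sum(event_types(res5$events) == "silence_reminder"), 1L)
  # sub-threshold gaps stay silent
  short <- run_speech_task(cfg, gap_speaker(cbind(start = 5, length = 0.8)))
  expect_identical(sum(event_types(short$events) == "silence_reminder"), 0L)
})

test_that("a completed session contains the full questionnaire schedule", {
  p <- fixture_participant("stress")
  log <- run_session(make_config("stress"), p, seed = 77)
  types <- event_types(log)
  q <- Filter(function(e) e$type == "questionnaire", log$events)
  inst <- vapply(q, function(e) e$payload$instrument, character(1))
  expect_identical(sum(inst == "panas"), 2L)
  expect_identical(sum(inst == "vas"), 3L)
  expect_identical(sum(inst == "elements"), 1L)
  expect_identical(types[1], "session_start")
  expect_identical(types[2], "framing_shown")
  expect_identical(types[length(types)], "session_end")
  # events are ordered in session time
  ts <- vapply(log$events, `[[`, numeric(1), "t")
  expect_true(all(diff(ts) >= 0))
})

test_that("a certain intro dropout truncates the log after the framing", {
  p <- fixture_participant("stress",
                           dropout = c(intro = 1, math = 0, intermediate = 0,
                                       speech = 0, post = 0))
  log <- run_session(make_config("stress"), p, seed = 78)
  expect_identical(event_types(log), c("session_start", "framing_shown", "dropout"))
})

test_that("sessions replay byte-identically under a fixed seed", {
  p <- fixture_participant("stress")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_session_log(run_session(make_config("stress"), p, seed = 123), f1)
  write_session_log(run_session(make_config("stress"), p, seed = 123), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed gives a different trajectory
  f3 <- withr::local_tempfile()
  write_session_log(run_session(make_config("stress"), p, seed = 124), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})
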