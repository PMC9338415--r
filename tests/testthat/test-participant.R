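test_that("degenerate skill profiles behave as configured", {
  pr <- generate_problem(make_config("stress"))
  mute <- skill_profile(p_no_input = 1)
  set.seed(1)
  for (i in 1:10) expect_null(respond_math(mute, pr, 3)$answer)
  sharp <- skill_profile(solve_median_s = c(add = 1e-4, sub = 1e-4,
                                            mul = 1e-4, div = 1e-4),
                         solve_log_sd = 0, base_accuracy = 1, p_no_input = 0)
  set.seed(2)
  for (i in 1:10) {
    r <- respond_math(sharp, pr, 0.5)
    expect_identical(r$answer, pr$solution)
    expect_lt(r$latency_s, 0.5)
  }
})

test_that("accuracy is non-increasing as the time limit tightens", {
  skill <- skill_profile(solve_median_s = c(add = 2, sub = 2, mul = 2, div = 2),
                         p_no_input = 0)
  pr <- generate_problem(make_config("control"))
  set.seed(33)
  acc <- vapply(c(5, 3, 2, 1), function(limit) {
    mean(replicate(4000, {
      r <- respond_math(skill, pr, limit)
      !is.null(r$answer) && r$answer == pr$solution
    }))
  }, numeric(1))
  expect_true(all(diff(acc) < 0.02))  # monotone up to Monte-Carlo noise
  expect_gt(acc[1], acc[4] + 0.2)
})

test_that("a permuted keypad slows responses down", {
  skill <- skill_profile(solve_log_sd = 0, p_no_input = 0)
  pr <- structure(list(op = "add", a = 2, b = 3, solution = 5, rescue = FALSE),
                  class = "dst_problem")
  set.seed(4)
  plain <- respond_math(skill, pr, 30, keypad = 1:10)
  swapped <- respond_math(skill, pr, 30, keypad = c(2:10, 1))
  expect_equal(swapped$latency_s - plain$latency_s, skill$swap_penalty_s)
})

test_that("default dropout hazards reproduce the observed completion fractions", {
  for (cond in c("stress", "control")) {
    hz <- default_dropout(cond)
    expect_true(all(hz >= 0 & hz < 1))
    expect_named(hz, c("intro", "math", "intermediate", "speech", "post"))
    target <- if (cond == "stress") 112 / 300 else 206 / 247
    expect_equal(prod(1 - hz), target, tolerance = 1e-12)
  }
  # most stress-arm attrition is front-loaded before the math task
  expect_gt(default_dropout("stress")[["intro"]],
            sum(default_dropout("stress")[-1]))
})

test_that("simulated cohorts complete at approximately the observed rates", {
  spec <- cohort_spec(300, 247, seed = 2024)
  res <- simulate_cohort(spec, completers_only = TRUE)
  done <- vapply(res$logs, function(l)
    any(event_types(l) == "session_end"), logical(1))
  arm <- vapply(res$logs, function(l) l$meta$condition, character(1))
  p_stress <- mean(done[arm == "stress"])
  p_control <- mean(done[arm == "control"])
  # binomial 99% bands around 0.373 (n = 300) and 0.834 (n = 247)
  expect_lt(abs(p_stress - 0.373), 2.6 * sqrt(0.373 * 0.627 / 300))
  expect_lt(abs(p_control - 0.834), 2.6 * sqrt(0.834 * 0.166 / 247))
})

test_that("exclusion flags follow the study's participant filters", {
  p_done <- fixture_participant("control")
  p_gone <- fixture_participant("control",
                                dropout = c(intro = 1, math = 0, intermediate = 0,
                                            speech = 0, post = 0))
  cfg <- make_config("control")
  complete <- run_session(cfg, p_done, seed = 1)
  dropout <- run_session(cfg, p_gone, seed = 2)
  expect_false(exclusion_flags(complete)[["excluded"]])
  expect_true(exclusion_flags(dropout)[["incomplete"]])
  expect_true(exclusion_flags(dropout)[["excluded"]])
  # unrealistic duration window
  expect_true(exclusion_flags(complete, min_duration_s = 1e5)[["duration_outlier"]])
  expect_true(exclusion_flags(complete, max_duration_s = 10)[["duration_outlier"]])
  # prior knowledge flag propagates from the participant metadata
  p_known <- fixture_participant("control", prior_knowledge = TRUE)
  known <- run_session(cfg, p_known, seed = 3)
  expect_true(exclusion_flags(known)[["prior_knowledge"]])

  # toy set: 10 logs, 2 incomplete, 1 prior knowledge -> 7 retained
  logs <- c(replicate(7, complete, simplify = FALSE),
            replicate(2, dropout, simplify = FALSE),
            list(known))
  flags <- vapply(logs, function(l) exclusion_flags(l)[["excluded"]], logical(1))
  expect_identical(sum(!flags), 7L)
})

test_that("exclusion bookkeeping reproduces the analyzable sample arithmetic", {
  s <- exclusion_summary(547, 229, 13, 19, 2)
  expect_identical(s$n_retained, 284)
  expect_identical(s$n_excluded, 263)
  expect_error(exclusion_summary(10, 9, 2, 0, 0))
  expect_equal(round(completion_fraction(206, 247), 1), 83.4)
  expect_equal(round(completion_fraction(112, 300), 1), 37.3)
})
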