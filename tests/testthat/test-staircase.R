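outcome <- function(kind) {
  structure(list(kind = kind,
                 latency_s = if (kind == "timeout_no_input") NA_real_ else 1),
            class = "dst_outcome")
}

apply_seq <- function(state, kinds, config) {
  for (k in kinds) state <- apply_outcome(state, outcome(k), config)
  state
}

test_that("streak rules fire at the published run lengths", {
  stress <- make_config("stress")
  st <- apply_seq(new_math_state(stress), rep("correct", 3), stress)
  expect_equal(st$time_limit_s, 2.7)
  expect_identical(st$swap_remaining, 4L)
  expect_identical(st$consecutive_correct, 0L)

  st <- apply_seq(new_math_state(stress), rep("wrong", 3), stress)
  expect_equal(st$time_limit_s, 3.3)
  expect_identical(st$consecutive_wrong_or_timeout, 0L)

  control <- make_config("control")
  st <- apply_seq(new_math_state(control), "wrong", control)
  expect_equal(st$time_limit_s, 5.5)
  st <- apply_seq(new_math_state(control), rep("correct", 4), control)
  expect_equal(st$time_limit_s, 4.5)
  expect_identical(st$swap_remaining, 0L)  # no swap window in control

  st <- apply_seq(new_math_state(stress), rep("timeout_no_input", 5), stress)
  expect_true(st$rescue_pending)
  expect_identical(st$consecutive_no_input, 0L)
})

test_that("timeouts feed the easier streak but keypresses reset the rescue counter", {
  stress <- make_config("stress")
  # wrong answers alone never trigger a rescue
  st <- apply_seq(new_math_state(stress), rep("wrong", 10), stress)
  expect_false(st$rescue_pending)
  # a wrong answer mid-run restarts the no-input count
  st <- apply_seq(new_math_state(stress),
                  c(rep("timeout_no_input", 4), "wrong",
                    rep("timeout_no_input", 4)), stress)
  expect_false(st$rescue_pending)
  st <- apply_outcome(st, outcome("timeout_no_input"), stress)
  expect_true(st$rescue_pending)
})

test_that("the unclamped limit is path independent in the adjustments", {
  stress <- make_config("stress", time_limit_bounds = c(1e-6, 1e6))
  set.seed(42)
  for (rep in 1:20) {
    a <- sample(0:4, 1)   # harder adjustments
    b <- sample(0:4, 1)   # easier adjustments
    blocks <- c(rep(list(rep("correct", 3)), a), rep(list(rep("wrong", 3)), b))
    blocks <- blocks[sample.int(length(blocks))]
    st <- apply_seq(new_math_state(stress), unlist(blocks), stress)
    expect_equal(st$time_limit_s, 3 * 0.9^a * 1.1^b, tolerance = 1e-12)
  }
})

test_that("the limit stays inside the configured clamp bounds", {
  stress <- make_config("stress")
  st <- apply_seq(new_math_state(stress), rep("correct", 3 * 60), stress)
  expect_equal(st$time_limit_s, stress$time_limit_bounds[1])
  st <- apply_seq(new_math_state(stress), rep("wrong", 3 * 80), stress)
  expect_equal(st$time_limit_s, stress$time_limit_bounds[2])
})

test_that("control limit never decreases except after a 4-correct run", {
  control <- make_config("control")
  set.seed(9)
  st <- new_math_state(control)
  streak <- 0L
  for (i in 1:500) {
    kind <- sample(c("correct", "wrong", "timeout_no_input"), 1,
                   prob = c(0.6, 0.25, 0.15))
    before <- st$time_limit_s
    st <- apply_outcome(st, outcome(kind), control)
    streak <- if (kind == "correct") streak + 1L else 0L
    if (st$time_limit_s < before) {
      expect_identical(streak, 4L)
      streak <- 0L
    }
  }
})

test_that("running percent correct counts timeouts in the denominator", {
  stress <- make_config("stress")
  expect_identical(percent_correct(new_math_state(stress)), 0)
  st <- apply_seq(new_math_state(stress),
                  c("correct", "correct", "timeout_no_input", "correct"), stress)
  expect_equal(percent_correct(st), 75)
  st <- apply_seq(new_math_state(stress), rep("timeout_no_input", 5), stress)
  expect_equal(percent_correct(st), 0)
})

test_that("equal up/down run lengths balance long-run accuracy near 50%", {
  stress <- make_config("stress")
  set.seed(101)
  sim <- simulate_staircase(stress, logistic_p(tau = 2, slope = 4), 10000)
  expect_gt(sim$accuracy, 0.47)
  expect_lt(sim$accuracy, 0.53)

  # brute-force Markov oracle: independent re-simulation of the streak rules
  set.seed(102)
  limit <- 3; cc <- 0; cw <- 0; hits <- 0
  p <- logistic_p(tau = 2, slope = 4)
  for (i in 1:10000) {
    ok <- runif(1) < p(limit)
    if (ok) { hits <- hits + 1; cc <- cc + 1; cw <- 0 } else { cw <- cw + 1; cc <- 0 }
    if (cc == 3) { limit <- max(0.5, limit * 0.9); cc <- 0 }
    if (cw == 3) { limit <- min(30, limit * 1.1); cw <- 0 }
  }
  expect_gt(hits / 10000, 0.47)
  expect_lt(hits / 10000, 0.53)
})
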