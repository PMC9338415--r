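## Arithmetic problem generation: constructive enumeration of the valid
## operand pairs per operation, sampled uniformly (op first, then pair).

# cache of valid (a, b) pair matrices per op; filled lazily
.pair_env <- new.env(parent = emptyenv())

#' Enumerate valid operand pairs for one operation
#'
#' A pair (a, b) with a, b in \[1, 99\] is valid for an operation when the
#' exact result is an integer in \[1, 99\] (division pairs must divide
#' evenly). Enumeration is exhaustive and cached per operation.
#'
#' @param op one of `"add"`, `"sub"`, `"mul"`, `"div"`.
#' @return integer matrix with columns `a`, `b`, `solution`.
#' @examples
#' nrow(valid_pairs("add"))  # 4851
#' nrow(valid_pairs("div"))  # 473
#' @export
valid_pairs <- function(op) {
  op <- match.arg(op, c("add", "sub", "mul", "div"))
  if (!is.null(.pair_env[[op]])) return(.pair_env[[op]])
  g <- expand.grid(a = 1:99, b = 1:99)
  s <- switch(op,
    add = g$a + g$b,
    sub = g$a - g$b,
    mul = g$a * g$b,
    div = ifelse(g$a %% g$b == 0L, g$a %/% g$b, NA_integer_))
  keep <- !is.na(s) & s >= 1L & s <= 99L
  m <- cbind(a = g$a[keep], b = g$b[keep], solution = as.integer(s[keep]))
  .pair_env[[op]] <- m
  m
}

#' Generate one arithmetic problem
#'
#' Draws the operation uniformly from the configured operation set, then an
#' operand pair uniformly from the exhaustively enumerated valid pairs for
#' that operation. A rescue problem is always an easy addition, regardless of
#' the configured set.
#'
#' @param config a [make_config()] object.
#' @param rescue logical; when `TRUE` the problem is an easily solvable
#'   addition (small operands), used after a run of silent trials.
#' @return A list of class `dst_problem` with fields `op`, `a`, `b`,
#'   `solution`, `rescue`.
#' @export
generate_problem <- function(config, rescue = FALSE) {
  if (rescue) {
    # easy summation: single-digit operands
    a <- sample.int(9L, 1L)
    b <- sample.int(9L, 1L)
    pr <- list(op = "add", a = a, b = b, solution = a + b, rescue = TRUE)
  } else {
    op <- if (length(config$allowed_ops) == 1L) config$allowed_ops
          else config$allowed_ops[sample.int(length(config$allowed_ops), 1L)]
    m <- valid_pairs(op)
    i <- sample.int(nrow(m), 1L)
    pr <- list(op = op, a = m[i, "a"], b = m[i, "b"],
               solution = m[i, "solution"], rescue = FALSE)
  }
  class(pr) <- "dst_problem"
  pr
}

#' Classify a typed response against a problem
#'
#' @param problem a `dst_problem`.
#' @param typed_answer integer answer, or `NULL` when no input was given.
#' @param latency_s time from problem onset to answer submission, seconds;
#'   ignored when `typed_answer` is `NULL`.
#' @param time_limit_s current staircase time limit, seconds.
#' @return A list of class `dst_outcome` with `kind` (`"correct"`, `"wrong"`
#'   or `"timeout_no_input"`) and `latency_s` (`NA` for timeouts).
#' @export
classify_response <- function(problem, typed_answer, latency_s, time_limit_s) {
  if (is.null(typed_answer)) {
    out <- list(kind = "timeout_no_input", latency_s = NA_real_)
  } else {
    if (!is.numeric(latency_s) || latency_s < 0)
      stop("latency must be a non-negative number of seconds", call. = FALSE)
    if (latency_s >= time_limit_s) {
      # an answer landing at/after the deadline is never registered
      out <- list(kind = "timeout_no_input", latency_s = NA_real_)
    } else if (typed_answer == problem$solution) {
      out <- list(kind = "correct", latency_s = latency_s)
    } else {
      out <- list(kind = "wrong", latency_s = latency_s)
    }
  }
  class(out) <- "dst_outcome"
  out
}

#' Keypad layout for the next task
#'
#' While a swap window is open (stress condition, after a tightening of the
#' time limit) each presented task gets a fresh uniformly random
#' non-identity permutation of the ten digit keys; otherwise the identity
#' layout. The control condition never swaps.
#'
#' @param state a `dst_math_state` (see [new_math_state()]).
#' @param config a [make_config()] object.
#' @return integer vector of length 10: position i shows digit
#'   `layout[i] - 1` (a permutation of 1:10 standing for digits 0-9).
#' @export
next_keypad <- function(state, config) {
  if (config$condition == "control" || state$swap_remaining <= 0L)
    return(1:10)
  repeat {
    p <- sample.int(10L)
    if (!identical(p, 1:10)) return(p)
  }
}
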