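#' Protocol configuration for one condition
#'
#' Builds the full constant set of the Digital Stress Test (\code{"stress"})
#' or its control variant (\code{"control"}). The stress condition uses a
#' 3-second initial time limit, all four arithmetic operations, a
#' 3-correct/3-wrong adaptive staircase with keypad swapping for the 4 tasks
#' after every tightening, a rescue rule after 5 consecutive no-input trials,
#' and a fabricated 75% comparison score. The control condition uses a
#' 5-second initial limit, addition only, an asymmetric 4-correct/1-wrong
#' staircase, and no swap, comparison or rescue machinery.
#'
#' @param condition `"stress"` or `"control"`.
#' @param ... named overrides for individual fields (advanced use; overrides
#'   are validated against the same invariants as the defaults).
#'
#' @return An object of class `dst_config`: a named list with fields
#'   `condition`, `math_duration_s`, `initial_time_limit_s`, `adapt_factor`,
#'   `harder_streak`, `easier_streak`, `swap_task_count`,
#'   `rescue_no_input_streak`, `rescue_enabled`, `comparison_pct`,
#'   `allowed_ops`, `operand_range`, `solution_range`, `n_speech_scenarios`,
#'   `prep_s`, `present_s`, `silence_reminder_s`, `time_limit_bounds`.
#' @examples
#' cfg <- make_config("stress")
#' cfg$initial_time_limit_s  # 3
#' make_config("control")$allowed_ops  # "add"
#' @export
make_config <- function(condition = c("stress", "control"), ...) {
  condition <- match.arg(condition)
  base <- list(
    condition = condition,
    math_duration_s = 90,
    adapt_factor = 0.10,
    operand_range = c(1L, 99L),
    solution_range = c(1L, 99L),
    n_speech_scenarios = 3L,
    prep_s = 10,
    present_s = 20,
    silence_reminder_s = 1.0,
    time_limit_bounds = c(0.5, 30)
  )
  if (condition == "stress") {
    cond <- list(
      initial_time_limit_s = 3.0,
      harder_streak = 3L,
      easier_streak = 3L,
      swap_task_count = 4L,
      rescue_no_input_streak = 5L,
      rescue_enabled = TRUE,
      comparison_pct = 75,
      allowed_ops = c("add", "sub", "mul", "div")
    )
  } else {
    cond <- list(
      initial_time_limit_s = 5.0,
      harder_streak = 4L,
      easier_streak = 1L,
      swap_task_count = 0L,
      rescue_no_input_streak = 5L,
      rescue_enabled = FALSE,
      comparison_pct = NA_real_,
      allowed_ops = "add"
    )
  }
  cfg <- utils::modifyList(c(base, cond), list(...))
  class(cfg) <- "dst_config"
  validate_config(cfg)
  cfg
}

#' Validate a protocol configuration
#'
#' Checks all structural invariants of a [make_config()] object and returns it
#' invisibly, stopping with a descriptive error on the first violation.
#'
#' @param cfg a `dst_config` object.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "dst_config"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg, call. = FALSE)
  chk(cfg$condition %in% c("stress", "control"), "unknown condition")
  for (f in c("math_duration_s", "initial_time_limit_s", "prep_s", "present_s",
              "silence_reminder_s")) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] > 0,
        paste(f, "must be a positive duration"))
  }
  chk(cfg$adapt_factor > 0 && cfg$adapt_factor < 1, "adapt_factor must lie in (0,1)")
  for (f in c("harder_streak", "easier_streak", "rescue_no_input_streak"))
    chk(cfg[[f]] >= 1, paste(f, "must be >= 1"))
  chk(cfg$swap_task_count >= 0, "swap_task_count must be >= 0")
  chk(identical(as.integer(cfg$operand_range), c(1L, 99L)) &&
        identical(as.integer(cfg$solution_range), c(1L, 99L)),
      "operand and solution ranges are fixed at [1, 99]")
  chk(all(cfg$allowed_ops %in% c("add", "sub", "mul", "div")) &&
        length(cfg$allowed_ops) >= 1, "allowed_ops must be a subset of add/sub/mul/div")
  if (cfg$condition == "control")
    chk(identical(cfg$allowed_ops, "add") && cfg$swap_task_count == 0L,
        "control condition is addition-only with no keypad swap")
  chk(length(cfg$time_limit_bounds) == 2 &&
        cfg$time_limit_bounds[1] > 0 &&
        cfg$time_limit_bounds[1] <= cfg$initial_time_limit_s &&
        cfg$initial_time_limit_s <= cfg$time_limit_bounds[2],
      "time_limit_bounds must contain initial_time_limit_s")
  invisible(cfg)
}

#' @export
print.dst_config <- function(x, ...) {
  cat(sprintf("<dst_config: %s condition>\n", x$condition))
  cat(sprintf("  math: %gs, initial limit %gs, staircase -%d%%/%d correct, +%d%%/%d wrong\n",
              x$math_duration_s, x$initial_time_limit_s,
              round(100 * x$adapt_factor), x$harder_streak,
              round(100 * x$adapt_factor), x$easier_streak))
  cat(sprintf("  ops: %s; swap %d tasks; rescue %s\n",
              paste(x$allowed_ops, collapse = ","), x$swap_task_count,
              if (x$rescue_enabled) sprintf("after %d silent tasks", x$rescue_no_input_streak)
              else "off"))
  cat(sprintf("  speech: %d scenarios, %gs prep + %gs present, %gs silence reminder\n",
              x$n_speech_scenarios, x$prep_s, x$present_s, x$silence_reminder_s))
  invisible(x)
}

#' Read or write a protocol configuration as YAML
#'
#' The YAML file carries the `dst_config` fields under their exact names.
#'
#' @param cfg a `dst_config` object.
#' @param path file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a validated `dst_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  out <- unclass(cfg)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- make_config(raw$condition)
  known <- setdiff(names(raw), "condition")
  unknown <- setdiff(known, names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (f in known) cfg[[f]] <- if (is.integer(cfg[[f]])) as.integer(raw[[f]]) else raw[[f]]
  validate_config(cfg)
  cfg
}
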