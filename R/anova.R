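## Split-plot (mixed-design) ANOVA: one between-subject factor (group), one
## within-subject factor (time). Fitted as a multivariate linear model with
## the repeated-measures machinery of car::Anova, which supplies the
## univariate split-plot decomposition, Mauchly's sphericity test and the
## Greenhouse-Geisser correction.

#' Mixed-design ANOVA with Greenhouse-Geisser correction
#'
#' Analyzes one outcome measure from a long table with a between-subject
#' `group` factor and a within-subject `time` factor. Participants without a
#' complete set of time levels are dropped listwise (and reported). With
#' three or more time levels, Mauchly's test and Greenhouse-Geisser
#' epsilon-corrected p values are included; with two levels sphericity holds
#' trivially and epsilon is exactly 1. Partial eta squared is reported per
#' effect. A single-group table yields the within-subject (time) effect
#' only.
#'
#' @param table long data frame with columns `participant_id`, `group`,
#'   `time`, `value` (one measure; one row per participant-time).
#' @param time_levels optional explicit ordering of the time factor;
#'   defaults to `baseline`, `intermediate`, `post` filtered to the levels
#'   present.
#' @return object of class `dst_anova`: list with per-effect entries
#'   (`group`, `time`, `group_by_time` as applicable), each carrying `F`,
#'   `df1`, `df2`, `p`, `partial_eta2`, and for within-subject effects
#'   `gg_epsilon`, `p_gg`, `sphericity_p` (`NA` when the within factor has
#'   two levels); plus `n_per_group` and `excluded` (incomplete participant
#'   ids).
#' @export
mixed_anova <- function(table, time_levels = NULL) {
  req <- c("participant_id", "group", "time", "value")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stop("long table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (is.null(time_levels))
    time_levels <- intersect(c("baseline", "intermediate", "post"),
                             unique(table$time))
  k <- length(time_levels)
  stopifnot(k >= 2)
  if (anyDuplicated(table[c("participant_id", "time")]))
    stop("duplicate participant-by-time rows: supply one measure at a time",
         call. = FALSE)

  wide <- stats::reshape(
    table[c("participant_id", "group", "time", "value")],
    idvar = c("participant_id", "group"), timevar = "time",
    direction = "wide")
  ycols <- paste0("value.", time_levels)
  have <- intersect(ycols, names(wide))
  if (length(have) < k)
    stop("time level(s) absent from the table: ",
         paste(setdiff(time_levels, sub("^value\\.", "", have)), collapse = ", "),
         call. = FALSE)
  cc <- stats::complete.cases(wide[ycols])
  excluded <- wide$participant_id[!cc]
  wide <- wide[cc, , drop = FALSE]

  groups <- factor(wide$group)
  n_per_group <- table(groups)
  if (any(n_per_group < 2))
    stop("every group needs at least 2 complete participants", call. = FALSE)
  Y <- as.matrix(wide[ycols])
  colnames(Y) <- time_levels
  idata <- data.frame(time = factor(time_levels, levels = time_levels))

  two_group <- nlevels(groups) >= 2
  mlm <- if (two_group) stats::lm(Y ~ groups) else stats::lm(Y ~ 1)
  av <- suppressMessages(car::Anova(mlm, idata = idata, idesign = ~time, type = 2))
  # Huynh-Feldt epsilon > 1 is routinely capped; the warning is noise here
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests

  eff_row <- function(row) {
    list(F = unname(ut[row, "F value"]),
         df1 = unname(ut[row, "num Df"]),
         df2 = unname(ut[row, "den Df"]),
         p = unname(ut[row, "Pr(>F)"]),
         partial_eta2 = unname(ut[row, "Sum Sq"] /
                                 (ut[row, "Sum Sq"] + ut[row, "Error SS"])))
  }
  add_gg <- function(eff, row) {
    if (k == 2) {
      eff$gg_epsilon <- 1
      eff$p_gg <- eff$p
      eff$sphericity_p <- NA_real_
    } else {
      pa <- s$pval.adjustments
      st <- s$sphericity.tests
      eff$gg_epsilon <- unname(pa[row, "GG eps"])
      eff$p_gg <- unname(pa[row, "Pr(>F[GG])"])
      eff$sphericity_p <- unname(st[row, "p-value"])
    }
    eff
  }

  out <- list()
  if (two_group) out$group <- eff_row("groups")
  out$time <- add_gg(eff_row("time"), "time")
  if (two_group) out$group_by_time <- add_gg(eff_row("groups:time"), "groups:time")
  out$n_per_group <- as.list(n_per_group)
  out$excluded <- as.character(excluded)
  class(out) <- "dst_anova"
  out
}

#' @export
print.dst_anova <- function(x, ...) {
  for (eff in intersect(c("group", "time", "group_by_time"), names(x))) {
    e <- x[[eff]]
    gg <- if (!is.null(e$gg_epsilon) && e$gg_epsilon < 1)
      sprintf(", GG eps = %.3f, p[GG] = %.4g", e$gg_epsilon, e$p_gg) else ""
    cat(sprintf("%-14s F(%g, %g) = %.3f, p = %.4g, eta_p^2 = %.3f%s\n",
                eff, e$df1, e$df2, e$F, e$p, e$partial_eta2, gg))
  }
  invisible(x)
}
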