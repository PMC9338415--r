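## Full evaluation pipeline over a scored questionnaire long table: per
## measure, assumption checks, mixed ANOVA, Bonferroni-adjusted Welch post
## hoc tests at each post-baseline timepoint, paired pre/post t tests and
## both Cohen's d variants per group.

#' Evaluate a study from its questionnaire long table
#'
#' Orchestrates the statistical pipeline for every measure present in the
#' table. For each measure: Shapiro-Wilk normality per group at each
#' timepoint and Levene variance homogeneity across groups (advisory), the
#' mixed-design ANOVA ([mixed_anova()]), Welch group comparisons at every
#' post-baseline timepoint with Bonferroni adjustment over that measure's
#' family, and per-group baseline-to-post paired t tests with both effect
#' size variants. With a single group, group comparisons are omitted and
#' the time effect is still computed.
#'
#' @param table long data frame (`participant_id`, `group`, `time`,
#'   `measure`, `value`).
#' @param measures subset of measures to analyze; default all present.
#' @return object of class `dst_report`: named list per measure with
#'   `assumptions`, `anova`, `posthoc`, `paired`, `effect_sizes`,
#'   `excluded`; plus a `design` element (`groups`, `n_participants`).
#' @export
evaluate_study <- function(table, measures = NULL) {
  req <- c("participant_id", "group", "time", "measure", "value")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("long table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(measures)) measures <- unique(table$measure)
  groups <- sort(unique(table$group))
  report <- list(design = list(groups = groups,
                               n_participants = length(unique(table$participant_id))))
  for (ms in measures) {
    sub <- table[table$measure == ms, , drop = FALSE]
    report[[ms]] <- evaluate_measure(sub, groups)
  }
  class(report) <- "dst_report"
  report
}

evaluate_measure <- function(sub, groups) {
  an <- mixed_anova(sub)
  complete_ids <- setdiff(unique(sub$participant_id), an$excluded)
  sub <- sub[sub$participant_id %in% complete_ids, , drop = FALSE]
  time_levels <- intersect(c("baseline", "intermediate", "post"),
                           unique(sub$time))

  cell <- function(g, tp) sub$value[sub$group == g & sub$time == tp]

  # advisory assumption checks per timepoint
  assumptions <- lapply(stats::setNames(time_levels, time_levels), function(tp) {
    samples <- lapply(groups, function(g) cell(g, tp))
    names(samples) <- groups
    samples <- Filter(function(s) length(s) >= 3, samples)
    res <- tryCatch(check_assumptions(samples), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    list(shapiro_p = stats::setNames(res$shapiro$p, names(samples)),
         levene_p = if (is.null(res$levene)) NA_real_ else res$levene$p)
  })

  # Welch group comparisons at each post-baseline timepoint, Bonferroni
  posthoc <- NULL
  if (length(groups) >= 2) {
    tps <- setdiff(time_levels, "baseline")
    raw <- lapply(tps, function(tp) welch_t(cell(groups[1], tp), cell(groups[2], tp)))
    padj <- bonferroni(vapply(raw, `[[`, numeric(1), "p"))
    posthoc <- lapply(seq_along(tps), function(i)
      list(time = tps[i], comparison = paste(groups[1], "vs", groups[2]),
           t = raw[[i]]$t, df = raw[[i]]$df, p = raw[[i]]$p,
           p_bonferroni = padj[i]))
    names(posthoc) <- tps
  }

  # per-group baseline -> post change: paired t and both d variants
  paired <- list()
  effect_sizes <- list()
  if ("post" %in% time_levels) {
    for (g in groups) {
      ids <- unique(sub$participant_id[sub$group == g])
      pre <- sub$value[sub$group == g & sub$time == "baseline"][
        match(ids, sub$participant_id[sub$group == g & sub$time == "baseline"])]
      post <- sub$value[sub$group == g & sub$time == "post"][
        match(ids, sub$participant_id[sub$group == g & sub$time == "post"])]
      pt <- tryCatch(paired_t(pre, post), error = function(e) NULL)
      if (is.null(pt)) next
      paired[[g]] <- pt
      effect_sizes[[g]] <- list(
        change_sd = cohen_d_change(pt$mean_change, pt$sd_change, pt$n),
        pooled_prepost = cohen_d_pooled_prepost(mean(pre), stats::sd(pre),
                                                mean(post), stats::sd(post),
                                                pt$n))
    }
  }

  list(assumptions = assumptions, anova = an, posthoc = posthoc,
       paired = paired, effect_sizes = effect_sizes,
       excluded = an$excluded)
}

#' @export
print.dst_report <- function(x, ...) {
  cat(sprintf("<dst_report: %d participants, groups: %s>\n",
              x$design$n_participants, paste(x$design$groups, collapse = ", ")))
  for (ms in setdiff(names(x), "design")) {
    cat("\n==", ms, "==\n")
    print(x[[ms]]$anova)
    if (!is.null(x[[ms]]$posthoc)) {
      for (ph in x[[ms]]$posthoc)
        cat(sprintf("  post hoc %-12s %s: t = %.3f, p_bonf = %.4g\n",
                    ph$time, ph$comparison, ph$t, ph$p_bonferroni))
    }
    for (g in names(x[[ms]]$effect_sizes)) {
      es <- x[[ms]]$effect_sizes[[g]]
      cat(sprintf("  %s pre/post d: %.3f (pooled), %.3f (change-SD)\n",
                  g, es$pooled_prepost$d, es$change_sd$d))
    }
  }
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' Serializes a [evaluate_study()] report with stable, sorted keys and full
#' numeric precision.
#'
#' @param report a `dst_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  strip_classes <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  }
  x <- strip_classes(report)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}
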