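## Two-step meta-analysis of standardized affect changes: per-study effect
## sizes, then an inverse-change-variance weighted combination. Weights are
## 1 / change_sd^2 (no sample-size factor) on absolute effect sizes; both
## conventions are what reproduces the published combined values.

#' Combine per-study effect sizes by inverse change variance
#'
#' Computes `w_i = 1 / change_sd_i^2` and the weighted mean of the absolute
#' per-study standardized effects, `sum(w_i * |d_i|) / sum(w_i)`.
#'
#' @param d per-study standardized effect sizes.
#' @param change_sd per-study change-score SDs (> 0).
#' @param label optional study labels.
#' @return object of class `dst_meta`: `combined_d`, `weights` and
#'   `per_study` (data frame with `label`, `d`, `change_sd`, `weight`,
#'   `contribution`).
#' @examples
#' meta_combine(c(1.015, 0.694, 0.281, 0.655),
#'              c(0.68, 0.44, 0.68, 0.53))$combined_d  # ~0.668
#' @export
meta_combine <- function(d, change_sd, label = paste0("study", seq_along(d))) {
  if (length(d) == 0L) stop("at least one study is required", call. = FALSE)
  stopifnot(length(change_sd) == length(d), all(change_sd > 0), all(is.finite(d)))
  w <- 1 / change_sd^2
  combined <- sum(w * abs(d)) / sum(w)
  structure(list(
    combined_d = combined,
    weights = w,
    per_study = data.frame(label = label, d = d, change_sd = change_sd,
                           weight = w, contribution = w * abs(d) / sum(w),
                           stringsAsFactors = FALSE)),
    class = "dst_meta")
}

#' @export
print.dst_meta <- function(x, ...) {
  cat(sprintf("<dst_meta: %d studies, combined |d| = %.3f>\n",
              nrow(x$per_study), x$combined_d))
  print(x$per_study, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Read a study-summary table
#'
#' Reads a CSV of per-study PANAS summary statistics with columns `study`,
#' `role` (`"dst"` or `"tsst"`), `subscale` (`"NA"`/`"PA"`), `pre_mean`,
#' `pre_sd`, `post_mean`, `post_sd`, `change_mean`, `change_sd`, `n`. The
#' bundled default mirrors the published comparison table.
#'
#' @param path CSV path; default is the bundled table.
#' @return data frame.
#' @export
read_study_summaries <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table2_studies.csv", package = "dstsim")
  # the subscale column holds the literal string "NA" (negative affect)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  req <- c("study", "role", "subscale", "pre_mean", "pre_sd", "post_mean",
           "post_sd", "change_mean", "change_sd", "n")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("study summary table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab
}

#' Two-step meta-analysis of one PANAS subscale
#'
#' Step one computes a per-study standardized effect size (selected
#' variant) and paired t test from the summary statistics; step two combines
#' the reference (TSST) studies with [meta_combine()] and reports the
#' smartphone (DST) study's effect alongside.
#'
#' @param studies data frame as from [read_study_summaries()].
#' @param subscale `"NA"` or `"PA"`.
#' @param variant `"pooled_prepost"` (default; reproduces the published
#'   table) or `"change_sd"`.
#' @return list with `per_study` (data frame incl. `d`, `t`, `df`, `p`),
#'   `combined` (a `dst_meta` over the TSST studies), `dst_d` and `variant`.
#' @export
meta_analyze <- function(studies, subscale = c("NA", "PA"),
                         variant = c("pooled_prepost", "change_sd")) {
  subscale <- match.arg(subscale)
  variant <- match.arg(variant)
  rows <- studies[studies$subscale == subscale, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no rows for subscale ", subscale, call. = FALSE)
  rows$d <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    if (variant == "pooled_prepost")
      cohen_d_pooled_prepost(r$pre_mean, r$pre_sd, r$post_mean, r$post_sd, r$n)$d
    else
      cohen_d_change(r$change_mean, r$change_sd, r$n)$d
  }, numeric(1))
  tt <- lapply(seq_len(nrow(rows)), function(i)
    paired_t_from_summary(rows$change_mean[i], rows$change_sd[i], rows$n[i]))
  rows$t <- vapply(tt, `[[`, numeric(1), "t")
  rows$df <- vapply(tt, `[[`, numeric(1), "df")
  rows$p <- vapply(tt, `[[`, numeric(1), "p")
  ref <- rows[rows$role == "tsst", , drop = FALSE]
  combined <- if (nrow(ref))
    meta_combine(ref$d, ref$change_sd, label = ref$study) else NULL
  dst_d <- if (any(rows$role == "dst")) rows$d[rows$role == "dst"][1] else NA_real_
  list(per_study = rows, combined = combined, dst_d = dst_d, variant = variant)
}
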