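## Elementary statistical building blocks of the evaluation pipeline.
## Standard tests are delegated to stats/car; the effect-size conventions
## (two Cohen's d variants, partial eta^2 from F and df) are defined here.

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk normality per sample and (for two or more samples) Levene's
#' test of variance homogeneity. The checks are advisory: the evaluation
#' pipeline reports them but proceeds with ANOVA regardless, relying on its
#' robustness to moderate non-normality.
#'
#' @param ... two or more numeric samples, or a single list of samples; a
#'   single sample gives only the normality check.
#' @return list with `shapiro` (per-sample data frame `W`, `p`) and `levene`
#'   (`F`, `df1`, `df2`, `p`; `NULL` for a single sample).
#' @export
check_assumptions <- function(...) {
  samples <- list(...)
  if (length(samples) == 1L && is.list(samples[[1]])) samples <- samples[[1]]
  for (s in samples) {
    if (length(s) < 3L) stop("each sample needs n >= 3", call. = FALSE)
    if (stats::sd(s) == 0)
      stop("constant sample: normality is undefined for degenerate input",
           call. = FALSE)
  }
  sw <- do.call(rbind, lapply(samples, function(s) {
    r <- stats::shapiro.test(s)
    data.frame(W = unname(r$statistic), p = r$p.value)
  }))
  lev <- NULL
  if (length(samples) >= 2L) {
    y <- unlist(samples)
    g <- factor(rep(seq_along(samples), lengths(samples)))
    lt <- car::leveneTest(y, g, center = stats::median)
    lev <- list(F = lt[1, "F value"], df1 = lt[1, "Df"], df2 = lt[2, "Df"],
                p = lt[1, "Pr(>F)"])
  }
  list(shapiro = sw, levene = lev)
}

#' Paired t test on pre/post scores
#'
#' Two-tailed paired t test with `df = n - 1`; the statistic is
#' `mean(post - pre) / (sd(post - pre) / sqrt(n))`.
#'
#' @param pre,post equal-length paired numeric vectors.
#' @return list of class `dst_ttest`: `t`, `df`, `p`, `n`, `mean_change`,
#'   `sd_change`.
#' @export
paired_t <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  ch <- post - pre
  if (stats::sd(ch) == 0)
    stop("zero change variance: paired t is undefined", call. = FALSE)
  r <- stats::t.test(post, pre, paired = TRUE)
  structure(list(t = unname(r$statistic), df = unname(r$parameter),
                 p = r$p.value, n = length(pre),
                 mean_change = mean(ch), sd_change = stats::sd(ch)),
            class = "dst_ttest")
}

#' Paired t from printed change summary statistics
#'
#' Recomputes the paired t statistic from a change-score mean and SD at a
#' given sample size, for working with published summary tables.
#'
#' @param change_mean,change_sd summary statistics of the change scores.
#' @param n sample size.
#' @return list of class `dst_ttest` (`t`, `df`, `p`, `n`).
#' @export
paired_t_from_summary <- function(change_mean, change_sd, n) {
  stopifnot(change_sd > 0, n >= 2)
  t <- change_mean / (change_sd / sqrt(n))
  df <- n - 1
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), n = n,
                 mean_change = change_mean, sd_change = change_sd),
            class = "dst_ttest")
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom, the
#' post hoc comparison used for unequal arm sizes and variance
#' heterogeneity.
#'
#' @param x,y numeric samples (n >= 2 each, not both constant).
#' @return list of class `dst_ttest`: `t`, `df`, `p`, `n1`, `n2`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("both samples are constant: Welch t is undefined", call. = FALSE)
  r <- stats::t.test(x, y, var.equal = FALSE)
  structure(list(t = unname(r$statistic), df = unname(r$parameter),
                 p = r$p.value, n1 = length(x), n2 = length(y)),
            class = "dst_ttest")
}

#' @export
print.dst_ttest <- function(x, ...) {
  cat(sprintf("t = %.3f, df = %.2f, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' @param pvals numeric p values in \[0, 1\].
#' @param m family size; defaults to `length(pvals)`.
#' @return adjusted p values, `pmin(pvals * m, 1)`.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  pmin(pvals * m, 1)
}

#' Cohen's d for change scores (d_z)
#'
#' Standardized mean change using the change-score SD:
#' `d = change_mean / change_sd`.
#'
#' @param change_mean,change_sd change-score summary statistics
#'   (`change_sd > 0`).
#' @param n optional sample size, carried through for standard errors.
#' @return list of class `dst_effect_size` with `d`, `variant = "change_sd"`,
#'   `se` (when `n` given) and `n`.
#' @export
cohen_d_change <- function(change_mean, change_sd, n = NA_integer_) {
  stopifnot(change_sd > 0)
  d <- change_mean / change_sd
  se <- if (is.na(n)) NA_real_ else sqrt(1 / n + d^2 / (2 * n))
  structure(list(d = d, variant = "change_sd", se = se, n = n),
            class = "dst_effect_size")
}

#' Cohen's d for pre/post means with pooled pre/post SD
#'
#' Standardized mean change dividing by the root mean of the pre and post
#' variances: `d = (m2 - m1) / sqrt((sd1^2 + sd2^2) / 2)`. This is the
#' variant that reproduces the published per-study effect sizes from their
#' printed pre/post summary statistics (see the methods vignette for the
#' labeling discrepancy with d_z).
#'
#' @param m1,sd1 pre mean and SD (`sd1 > 0`).
#' @param m2,sd2 post mean and SD (`sd2 > 0`).
#' @param n optional sample size.
#' @return list of class `dst_effect_size` with `d`,
#'   `variant = "pooled_prepost"`, `se`, `n`.
#' @examples
#' cohen_d_pooled_prepost(1.57, 0.56, 1.84, 0.70)$d  # ~0.426
#' @export
cohen_d_pooled_prepost <- function(m1, sd1, m2, sd2, n = NA_integer_) {
  stopifnot(sd1 > 0, sd2 > 0)
  d <- (m2 - m1) / sqrt((sd1^2 + sd2^2) / 2)
  se <- if (is.na(n)) NA_real_ else sqrt(1 / n + d^2 / (2 * n))
  structure(list(d = d, variant = "pooled_prepost", se = se, n = n),
            class = "dst_effect_size")
}

#' @export
print.dst_effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (%s variant)\n", x$d, x$variant))
  invisible(x)
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, algebraically identical to
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom (> 0).
#' @return value in \[0, 1\].
#' @examples
#' partial_eta2(31.37, 1, 282)  # ~0.10
#' @export
partial_eta2 <- function(F, df1, df2) {
  stopifnot(all(F >= 0), all(df1 > 0), all(df2 > 0))
  F * df1 / (F * df1 + df2)
}
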