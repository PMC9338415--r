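## Affect-outcome generator. Baseline subscale scores are shifted-gamma
## (right-skewed, floor-respecting, exact mean/SD); change scores are latent
## normal added to the baseline and clamped to the instrument range, with the
## latent change mean/SD moment-matched numerically so that the *realized*
## clamped change moments equal the configured targets.

# run expr under a temporary RNG state, restoring the caller's stream
with_local_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.calib_env <- new.env(parent = emptyenv())

# latent (delta, sigma) such that clamp(base + N(delta, sigma), lo, hi) - base
# has the target mean/SD; common-random-numbers simulation + Nelder-Mead
calibrate_change <- function(base_mean, base_sd, lo, hi,
                             target_mean, target_sd, n = 20000L) {
  key <- paste(base_mean, base_sd, lo, hi, target_mean, target_sd, sep = "|")
  hit <- .calib_env[[key]]
  if (!is.null(hit)) return(hit)
  draws <- with_local_rng(909090L, {
    b <- sample_baseline(n, base_mean, base_sd, lo, hi)
    list(b = b, z = stats::rnorm(n))
  })
  obj <- function(par) {
    post <- pmin(hi, pmax(lo, draws$b + par[1] + exp(par[2]) * draws$z))
    ch <- post - draws$b
    (mean(ch) - target_mean)^2 + (stats::sd(ch) - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  res <- list(delta = fit$par[1], sigma = exp(fit$par[2]))
  .calib_env[[key]] <- res
  res
}

# shifted-gamma baseline with exact mean/SD on [lo, hi]
sample_baseline <- function(n, mean, sd, lo, hi) {
  if (sd <= 0 || mean <= lo) return(rep(max(mean, lo), n))
  mu <- mean - lo
  shape <- (mu / sd)^2
  pmin(hi, lo + stats::rgamma(n, shape = shape, scale = sd^2 / mu))
}

#' Affect profile for one study arm
#'
#' Defines, per outcome measure, the baseline distribution and the change
#' from baseline at each later timepoint. PANAS subscales live on the 1-5
#' score scale, VAS scales on 0-100. Configured change means/SDs are the
#' moments of the realized (range-clamped) change scores: the latent change
#' parameters are moment-matched at construction.
#'
#' @param panas_na,panas_pa `list(base = c(mean, sd), post = c(mean, sd))`
#'   where `post` gives the change from baseline.
#' @param vas named list of the four scales (`stressed`, `frustrated`,
#'   `overstrained`, `ashamed`), each
#'   `list(base = c(mean, sd), intermediate = c(mean, sd), post = c(mean, sd))`
#'   with changes from baseline.
#' @param measures optional character vector restricting the profile to a
#'   subset of measures (faster when only one outcome is simulated).
#' @return object of class `dst_affect_profile`.
#' @export
affect_profile <- function(panas_na, panas_pa, vas, measures = NULL) {
  spec <- list(panas_na = c(list(scale = c(1, 5)), panas_na),
               panas_pa = c(list(scale = c(1, 5)), panas_pa))
  for (v in names(vas))
    spec[[paste0("vas_", v)]] <- c(list(scale = c(0, 100)), vas[[v]])
  if (!is.null(measures)) spec <- spec[intersect(names(spec), measures)]
  prof <- lapply(spec, function(ch) {
    lo <- ch$scale[1]; hi <- ch$scale[2]
    tps <- setdiff(names(ch), c("scale", "base"))
    ch$latent <- lapply(ch[tps], function(tgt)
      calibrate_change(ch$base[1], ch$base[2], lo, hi, tgt[1], tgt[2]))
    ch
  })
  structure(prof, class = "dst_affect_profile")
}

#' Default affect parameter sets
#'
#' `"table2_default"` configures both arms of the default synthetic cohort:
#' the stress arm's PANAS negative-affect change is 0.27 (SD 0.61) from a
#' 1.57 (0.56) baseline and positive affect changes 0.29 (SD 0.61) from
#' 3.08 (0.65); the control arm's negative affect drifts -0.09 from a
#' 1.58 (0.58) baseline (same change SD, which the source tables do not
#' print for that arm). VAS scales follow the group-by-time pattern of the
#' study: a strong rise over the arithmetic task and partial recovery over
#' the speech task in the stress arm, much flatter in the control arm.
#' `"null"` removes every group and time effect (both arms identical, zero
#' change means) for calibration studies.
#'
#' @param name `"table2_default"` or `"null"`.
#' @param measures optional subset of measures, see [affect_profile()].
#' @return named list with elements `stress` and `control`, each a
#'   `dst_affect_profile`.
#' @export
affect_defaults <- function(name = c("table2_default", "null"), measures = NULL) {
  name <- match.arg(name)
  vas_shape <- function(base, int_d, post_d, base_sd = 22, chg_sd = 20)
    list(base = c(base, base_sd), intermediate = c(int_d, chg_sd),
         post = c(post_d, chg_sd))
  if (name == "table2_default") {
    stress <- affect_profile(
      panas_na = list(base = c(1.57, 0.56), post = c(0.27, 0.61)),
      panas_pa = list(base = c(3.08, 0.65), post = c(0.29, 0.61)),
      vas = list(stressed     = vas_shape(33, 24,  4),
                 frustrated   = vas_shape(25, 22,  6),
                 overstrained = vas_shape(25, 20,  4),
                 ashamed      = vas_shape(15, 15,  2, base_sd = 18, chg_sd = 18)),
      measures = measures)
    control <- affect_profile(
      panas_na = list(base = c(1.58, 0.58), post = c(-0.09, 0.61)),
      panas_pa = list(base = c(3.02, 0.65), post = c(0.31, 0.61)),
      vas = list(stressed     = vas_shape(33,  8, -8),
                 frustrated   = vas_shape(25,  6, -6),
                 overstrained = vas_shape(25,  5, -7),
                 ashamed      = vas_shape(15,  2, -5, base_sd = 18, chg_sd = 18)),
      measures = measures)
  } else {
    null_arm <- affect_profile(
      panas_na = list(base = c(1.57, 0.56), post = c(0, 0.61)),
      panas_pa = list(base = c(3.08, 0.65), post = c(0, 0.61)),
      vas = list(stressed     = vas_shape(33, 0, 0),
                 frustrated   = vas_shape(25, 0, 0),
                 overstrained = vas_shape(25, 0, 0),
                 ashamed      = vas_shape(15, 0, 0, base_sd = 18, chg_sd = 18)),
      measures = measures)
    stress <- control <- null_arm
  }
  list(stress = stress, control = control)
}

#' Draw one participant's questionnaire targets
#'
#' Samples, from the current RNG stream, the participant's subscale-level
#' scores at every timepoint: baseline from the shifted-gamma marginal, later
#' timepoints as baseline plus a calibrated latent-normal change, clamped to
#' the instrument range.
#'
#' @param profile a [affect_profile()] object.
#' @return list with `panas` (per-timepoint list of `na`/`pa` targets),
#'   `vas` (per-timepoint named vectors) and `elements` placeholder (`NULL`;
#'   filled by the cohort simulator).
#' @export
draw_affect <- function(profile) {
  vals <- lapply(profile, function(ch) {
    lo <- ch$scale[1]; hi <- ch$scale[2]
    b <- sample_baseline(1L, ch$base[1], ch$base[2], lo, hi)
    out <- c(baseline = b)
    for (tp in names(ch$latent)) {
      l <- ch$latent[[tp]]
      out[tp] <- min(hi, max(lo, b + stats::rnorm(1, l$delta, l$sigma)))
    }
    out
  })
  tps_panas <- c("baseline", "post")
  tps_vas <- c("baseline", "intermediate", "post")
  vas_names <- sub("^vas_", "", grep("^vas_", names(vals), value = TRUE))
  panas <- lapply(stats::setNames(tps_panas, tps_panas), function(tp)
    list(na = if ("panas_na" %in% names(vals)) vals$panas_na[[tp]],
         pa = if ("panas_pa" %in% names(vals)) vals$panas_pa[[tp]]))
  vas <- lapply(stats::setNames(tps_vas, tps_vas), function(tp) {
    v <- vapply(vas_names, function(nm) vals[[paste0("vas_", nm)]][[tp]], numeric(1))
    stats::setNames(v, vas_names)
  })
  list(panas = panas, vas = vas, elements = NULL)
}

#' Generate I-PANAS-SF item responses for one timepoint
#'
#' Converts the participant's latent subscale targets (negative and positive
#' affect on the 1-5 scale) into the ten integer Likert items: each
#' five-item subscale is set to the integer item total nearest to five times
#' the target, spread over the items in random order. The realized subscale
#' mean therefore differs from the target by at most 0.1.
#'
#' @param affect_state list with elements `na` and `pa`, latent subscale
#'   means in \[1, 5\].
#' @return named integer vector of 10 items (`na1..na5`, `pa1..pa5`), each
#'   in 1..5.
#' @export
sample_panas_items <- function(affect_state) {
  itemize <- function(m) {
    stopifnot(m >= 1, m <= 5)
    total <- max(5L, min(25L, as.integer(round(5 * m))))
    base <- total %/% 5L
    r <- total %% 5L
    items <- c(rep(base + 1L, r), rep(base, 5L - r))
    if (r > 0L) items <- items[sample.int(5L)]
    items
  }
  c(stats::setNames(itemize(affect_state$na), paste0("na", 1:5)),
    stats::setNames(itemize(affect_state$pa), paste0("pa", 1:5)))
}

#' Draw element-rating responses
#'
#' Samples one VAS rating (0-100) per protocol element from the bundled
#' default element table for the condition (clamped normal around the
#' per-element default mean/SD); elements not applicable to the condition
#' are `NA`.
#'
#' @param condition `"stress"` or `"control"`.
#' @return named numeric vector, one entry per element id.
#' @export
sample_element_ratings <- function(condition = c("stress", "control")) {
  condition <- match.arg(condition)
  tab <- element_defaults()
  m <- if (condition == "stress") tab$dst_mean else tab$cdst_mean
  s <- if (condition == "stress") tab$dst_sd else tab$cdst_sd
  v <- rep(NA_real_, nrow(tab))
  ok <- !is.na(m)
  v[ok] <- pmin(100, pmax(0, stats::rnorm(sum(ok), m[ok],
                                          ifelse(is.na(s[ok]), 0, s[ok]))))
  stats::setNames(v, tab$element)
}

#' Bundled element-rating defaults
#'
#' Per-element mean/SD used by the simulator for the post-study
#' element-rating questionnaire, one row per protocol element with `NA` for
#' condition-inapplicable elements (keypad swap, live comparison and camera
#' items in the control condition).
#'
#' @return data frame with columns `element`, `category`, `dst_mean`,
#'   `dst_sd`, `cdst_mean`, `cdst_sd`.
#' @export
element_defaults <- function() {
  path <- system.file("extdata", "element_defaults.csv", package = "dstsim")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
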