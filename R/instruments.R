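## Instrument scoring: I-PANAS-SF (10 Likert items, 5 per subscale, scored
## as subscale means on 1-5) and VAS (relative mark position on 0-100).

#' Score an I-PANAS-SF response
#'
#' The ten items split into five negative-affect and five positive-affect
#' items; each subscale is scored as the item mean, so both outcomes range
#' from 1 to 5. Item-to-subscale assignment follows the published
#' instrument; items may be supplied in any order when named (`na1..na5`,
#' `pa1..pa5`), or positionally with the first five taken as negative
#' affect. Any missing or out-of-range item invalidates the response.
#'
#' @param items integer vector of length 10 with values in 1..5.
#' @return list with `na` and `pa` subscale means.
#' @examples
#' score_panas(c(1, 2, 3, 4, 5, 3, 3, 3, 3, 3))  # na = 3, pa = 3
#' @export
score_panas <- function(items) {
  items <- unlist(items)
  if (length(items) != 10L)
    stop("an I-PANAS-SF response has exactly 10 items, got ", length(items),
         call. = FALSE)
  if (anyNA(items) || any(items < 1 | items > 5) || any(items != round(items)))
    stop("items must be integers in 1..5 with no missing values", call. = FALSE)
  if (!is.null(names(items)) && all(c(paste0("na", 1:5), paste0("pa", 1:5)) %in% names(items))) {
    na_items <- items[paste0("na", 1:5)]
    pa_items <- items[paste0("pa", 1:5)]
  } else {
    na_items <- items[1:5]
    pa_items <- items[6:10]
  }
  list(na = mean(na_items), pa = mean(pa_items))
}

#' Score a visual analogue scale mark
#'
#' The score is the relative distance of the mark from the left end of the
#' line, scaled to 0-100.
#'
#' @param mark_position distance of the mark from the left end.
#' @param line_length total line length (same units, > 0).
#' @return value in \[0, 100\].
#' @examples
#' vas_score(37, 100)  # 37
#' vas_score(5, 10)    # 50
#' @export
vas_score <- function(mark_position, line_length) {
  if (!is.numeric(line_length) || any(line_length <= 0))
    stop("line_length must be positive", call. = FALSE)
  if (any(mark_position < 0) || any(mark_position > line_length))
    stop("mark_position must lie on the line", call. = FALSE)
  100 * mark_position / line_length
}

#' Rank protocol elements by mean perceived stress
#'
#' Computes per-element mean and SD of the element ratings and sorts them in
#' descending order of the mean; ties are broken alphabetically by element
#' label so the ranking is deterministic.
#'
#' @param ratings long data frame with columns `element` and `value` (one
#'   row per participant-element rating); rows with `NA` values are dropped.
#' @return data frame with columns `element`, `mean`, `sd`, `n`, ordered by
#'   descending mean.
#' @export
rank_elements <- function(ratings) {
  empty <- data.frame(element = character(), mean = numeric(),
                      sd = numeric(), n = integer(), stringsAsFactors = FALSE)
  if (nrow(ratings) == 0L) return(empty)
  ratings <- ratings[!is.na(ratings$value), , drop = FALSE]
  if (nrow(ratings) == 0L) return(empty)
  agg <- do.call(rbind, lapply(split(ratings$value, ratings$element), function(v)
    data.frame(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v))))
  agg$element <- rownames(agg)
  rownames(agg) <- NULL
  agg <- agg[order(-agg$mean, agg$element), c("element", "mean", "sd", "n")]
  rownames(agg) <- NULL
  agg
}

#' Bundled I-PANAS-SF item labels
#'
#' Item labels of the international short-form PANAS with their subscale
#' assignment (5 negative-affect, 5 positive-affect items). The English
#' published wording is bundled as a documented placeholder; the deployed
#' study language is not modeled.
#'
#' @return data frame with columns `item`, `label`, `subscale`.
#' @export
panas_items <- function() {
  path <- system.file("extdata", "panas_items.csv", package = "dstsim")
  # subscale codes are the literal strings "NA"/"PA"
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
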