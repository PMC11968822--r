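#' Immunoreactivity score (IRS)
#'
#' Semi-quantitative IHC score: the product of an ordinal score for the
#' proportion of positive cells (0: none, 1: 1--10%, 2: 11--50%,
#' 3: 51--80%, 4: 81--100%) and the staining intensity (0 negative, 1 mild,
#' 2 moderate, 3 intense), giving 0--12. Percentages falling strictly
#' between the printed integer bin edges (e.g. 10.5%) take the lower bin.
#' Categories: 0--1 no staining, 2--3 mild, 4--8 moderate, 9--12 strong.
#'
#' @param proportion_pct Percentage of positive cells in `[0, 100]`.
#' @param intensity Integer staining intensity in `0:3`.
#' @return List of class `irs_score`: `proportion_pct`, `proportion_score`,
#'   `intensity`, `irs`, `category`.
#' @export
irs <- function(proportion_pct, intensity) {
  if (!is.numeric(proportion_pct) || length(proportion_pct) != 1L ||
      is.na(proportion_pct) || proportion_pct < 0 || proportion_pct > 100) {
    stop("proportion_pct must be a single value in [0, 100]")
  }
  if (!intensity %in% 0:3) stop("intensity must be one of 0, 1, 2, 3")
  proportion_score <-
    if (proportion_pct < 1) 0L
    else if (proportion_pct < 11) 1L
    else if (proportion_pct < 51) 2L
    else if (proportion_pct < 81) 3L
    else 4L
  score <- proportion_score * as.integer(intensity)
  structure(
    list(proportion_pct = proportion_pct,
         proportion_score = proportion_score,
         intensity = as.integer(intensity),
         irs = score,
         category = irs_category(score)),
    class = "irs_score"
  )
}

#' Map an IRS value to its staining category
#'
#' @param score Integer IRS in 0--12.
#' @return One of `"no_staining"`, `"mild"`, `"moderate"`, `"strong"`.
#' @export
irs_category <- function(score) {
  if (!score %in% 0:12) stop("IRS must be an integer in 0..12")
  if (score <= 1) "no_staining"
  else if (score <= 3) "mild"
  else if (score <= 8) "moderate"
  else "strong"
}

#' Cells needed for a given library representation
#'
#' `n_guides * fold` cells maintain `fold`-times coverage of the library
#' (e.g. 250x representation of a 77,441-guide library needs 19,360,250
#' cells, i.e. at least 20 million when planning in millions).
#'
#' @param n_guides Number of library guides (>= 1).
#' @param fold Desired representation (> 0).
#' @return Exact cell count, `n_guides * fold`.
#' @export
coverage_cells <- function(n_guides, fold) {
  if (n_guides < 1) stop("n_guides must be >= 1")
  if (fold <= 0) stop("fold must be > 0")
  n_guides * fold
}

#' Round a cell count up to a planning unit
#'
#' Smallest multiple of `unit` that is >= `x` (e.g. unit 1e6 for "at least
#' N million cells").
#'
#' @param x Exact count (> 0).
#' @param unit Rounding unit (> 0).
#' @return Rounded count.
#' @export
round_up_to <- function(x, unit) {
  if (x <= 0 || unit <= 0) stop("x and unit must be > 0")
  ceiling(x / unit) * unit
}

#' Normalize a competitive-proliferation time course to day 0
#'
#' Rescales a series of percentages so the day-0 value is 100%; subsequent
#' values are multiplied by the same factor. Idempotent.
#'
#' @param values Numeric series of percentages.
#' @param days Numeric day labels aligned with `values`; day 0 must be
#'   present with a positive value. Defaults to `names(values)`.
#' @return Named numeric vector of rescaled values.
#' @export
normalize_timecourse <- function(values, days = NULL) {
  if (is.null(days)) {
    if (is.null(names(values))) stop("give `days` or name `values` by day")
    days <- as.numeric(names(values))
  }
  if (length(days) != length(values)) stop("days and values differ in length")
  i0 <- which(days == 0)
  if (length(i0) != 1L) stop("exactly one day-0 measurement required")
  if (is.na(values[i0]) || values[i0] <= 0) stop("day-0 value must be > 0")
  out <- values * 100 / values[i0]
  names(out) <- days
  out
}
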