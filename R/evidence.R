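#' Posterior probability of a sign
#'
#' Fraction of posterior draws with the stated sign. Draws exactly equal to
#' zero count toward neither sign.
#'
#' @param draws Numeric vector of posterior draws of a scalar parameter.
#' @param direction `"negative"` or `"positive"`.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' prob_of_sign(c(-1, -2, 3), "negative")
prob_of_sign <- function(draws, direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  if (length(draws) == 0) abort("`draws` is empty.")
  if (length(draws) < 1000) {
    warn("Fewer than 1,000 draws; sign probabilities may be unstable.")
  }
  if (direction == "negative") mean(draws < 0) else mean(draws > 0)
}

#' Grade evidence for a slope from its sign probability
#'
#' The "language of evidence" grading used for slope estimates: a posterior
#' sign probability of at least 0.95 is strong evidence, 0.90 moderate, 0.80
#' weak, and anything lower no evidence. This avoids a single binary
#' significance threshold.
#'
#' @param p_sign Posterior probability of the stated sign, in `[0, 1]`.
#' @return One of `"strong"`, `"moderate"`, `"weak"`, `"none"`.
#' @export
#' @examples
#' classify_slope_evidence(0.967) # "strong"
classify_slope_evidence <- function(p_sign) {
  if (any(p_sign < 0 | p_sign > 1)) abort("`p_sign` must be in [0, 1].")
  cut_points <- c(-Inf, 0.80, 0.90, 0.95, Inf)
  labels <- c("none", "weak", "moderate", "strong")
  labels[findInterval(p_sign, cut_points)]
}

#' Grade evidence from credible-interval overlap
#'
#' Non-overlapping 95% credible intervals demonstrate strong evidence of a
#' difference; otherwise non-overlapping 80% intervals demonstrate weak
#' evidence; otherwise there is no evidence. `interval_b` may be a point
#' (e.g. zero).
#'
#' @param interval_a A list/row with `l95`, `u95`, `l80`, `u80` (the 80%
#'   interval nested inside the 95% interval).
#' @param interval_b Same structure, or a single number treated as a point.
#' @return One of `"strong"`, `"weak"`, `"none"`.
#' @export
classify_interval_evidence <- function(interval_a, interval_b) {
  as_iv <- function(z) {
    if (is.numeric(z) && length(z) == 1) {
      list(l95 = z, u95 = z, l80 = z, u80 = z)
    } else {
      as.list(z)
    }
  }
  a <- as_iv(interval_a); b <- as_iv(interval_b)
  for (iv in list(a, b)) {
    if (iv$l80 < iv$l95 - 1e-12 || iv$u80 > iv$u95 + 1e-12) {
      abort("80% interval must be nested inside the 95% interval.")
    }
  }
  disjoint <- function(l1, u1, l2, u2) u1 < l2 || u2 < l1
  if (disjoint(a$l95, a$u95, b$l95, b$u95)) return("strong")
  if (disjoint(a$l80, a$u80, b$l80, b$u80)) return("weak")
  "none"
}

#' Baseline envelope test
#'
#' Tests for change relative to a historical baseline: strong evidence of
#' change is declared when no recent-year 95% posterior-predictive interval
#' contains (envelopes) the baseline value. Intervals are closed, so a
#' baseline equal to a bound counts as contained (conservative toward "no
#' change"). The first year after which containment never recurs is also
#' reported, to express findings like "change after 1999".
#'
#' @param intervals Tibble with columns `year`, `pi_low`, `pi_high` (95%
#'   posterior-predictive bounds), e.g. from [posterior_predict()].
#' @param baseline Baseline metric value.
#' @return A list: `per_year` (tibble with `year`, `contains_baseline`),
#'   `strong_change` (logical), `transition_year` (first year of the final
#'   uninterrupted run of non-containment, `NA` if none).
#' @export
baseline_envelope_test <- function(intervals, baseline) {
  stopifnot(all(c("year", "pi_low", "pi_high") %in% names(intervals)))
  if (nrow(intervals) == 0) abort("Need at least one predictive interval.")
  iv <- dplyr::arrange(intervals, .data$year)
  contains <- baseline >= iv$pi_low & baseline <= iv$pi_high
  strong <- !any(contains)
  transition <- NA
  if (any(!contains)) {
    last_contained <- max(which(contains), 0)
    if (last_contained < nrow(iv)) transition <- iv$year[last_contained + 1]
  }
  list(
    per_year = tibble::tibble(year = iv$year, contains_baseline = contains),
    strong_change = strong,
    transition_year = transition
  )
}

#' Count strong population changes from a CI table
#'
#' Counts taxa whose 95% confidence interval for the log response ratio
#' excludes zero (strong evidence of change), split into declines (upper
#' bound below 0) and increases (lower bound above 0). Because published
#' tables round bounds to one decimal, a second, rounding-aware convention
#' treats printed bounds equal to 0.0 as rounded away from zero (exclusive);
#' both conventions are always reported.
#'
#' @param table Tibble with columns `ci_low`, `ci_high` (one row per taxon).
#' @return Tibble with one row per convention (`strict`, `printed_rounding`)
#'   and columns `n_strong`, `n_declines`, `n_increases`.
#' @export
count_strong_changes <- function(table) {
  stopifnot(all(c("ci_low", "ci_high") %in% names(table)))
  if (any(is.na(table$ci_low) | is.na(table$ci_high))) {
    abort("CI bounds must be present for every taxon.")
  }
  count_one <- function(strict) {
    dec <- if (strict) table$ci_high < 0 else table$ci_high <= 0
    inc <- if (strict) table$ci_low > 0 else table$ci_low >= 0
    tibble::tibble(
      convention = if (strict) "strict" else "printed_rounding",
      n_strong = sum(dec | inc),
      n_declines = sum(dec),
      n_increases = sum(inc)
    )
  }
  dplyr::bind_rows(count_one(TRUE), count_one(FALSE))
}
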