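#' Maximum-temperature covariate for one survey
#'
#' Reduces a daily sea-surface temperature series to the covariate used for
#' attribution: the empirical 90th percentile of daily SST over the 365-day
#' window ending the day before the survey reference date, so the hypothesized
#' cause (temperature) strictly precedes the effect (the surveyed community).
#' Extreme rather than average temperature is used because extremes are the
#' physiologically relevant driver on the shore.
#'
#' @param series Tibble with columns `date` (Date, unique, sorted) and
#'   `sst_c` (degrees C).
#' @param survey_ref_date Reference date of the survey (Date or parseable
#'   string).
#' @param min_days Minimum number of daily observations required in the
#'   window (default 200); below this the covariate is returned missing with
#'   a warning, because a percentile over sparse coverage is misleading.
#' @param prob Percentile (default 0.9). The linear-interpolation quantile
#'   convention (type 7) is used and recorded in the output.
#' @return A one-row tibble: `t_max_p90`, `window_start`, `window_end`,
#'   `n_days_used`, `quantile_type`.
#' @export
#' @examples
#' s <- tibble::tibble(date = seq(as.Date("2000-01-01"), by = "day", length.out = 400),
#'                     sst_c = 13)
#' max_sst_p90(s, "2001-01-15")
max_sst_p90 <- function(series, survey_ref_date, min_days = 200, prob = 0.9) {
  stopifnot(all(c("date", "sst_c") %in% names(series)))
  d <- as.Date(series$date)
  if (anyDuplicated(d)) abort("Temperature series has duplicate dates.")
  if (is.unsorted(d)) abort("Temperature series dates must be sorted.")
  ref <- as.Date(survey_ref_date)
  w_end <- ref - 1
  w_start <- ref - 365
  in_win <- d >= w_start & d <= w_end & !is.na(series$sst_c)
  n_used <- sum(in_win)
  val <- if (n_used < min_days) {
    warn(sprintf("Only %d of %d required days in the pre-survey window; covariate set to NA.",
                 n_used, min_days))
    NA_real_
  } else {
    unname(quantile(series$sst_c[in_win], prob, type = 7))
  }
  tibble::tibble(
    t_max_p90 = val, window_start = w_start, window_end = w_end,
    n_days_used = n_used, quantile_type = 7L
  )
}

#' Temperature covariates for a set of surveys
#'
#' Applies [max_sst_p90()] to each survey year. When a survey's day is
#' unknown, the prior calendar year is used as the window (Jan 1 of the survey
#' year as the reference date); the window bounds in the output make the
#' choice auditable.
#'
#' @inheritParams max_sst_p90
#' @param surveys Tibble with `year` and optionally `date` (first survey
#'   date of that year).
#' @return Tibble: one row per survey year with `year` plus the columns of
#'   [max_sst_p90()]. Years whose covariate is missing are retained here and
#'   excluded from model fitting downstream.
#' @export
covariates_for_surveys <- function(series, surveys, min_days = 200, prob = 0.9) {
  stopifnot("year" %in% names(surveys))
  purrr::map_dfr(seq_len(nrow(surveys)), function(i) {
    yr <- surveys$year[i]
    ref <- if ("date" %in% names(surveys) && !is.na(surveys$date[i])) {
      as.Date(surveys$date[i])
    } else {
      as.Date(sprintf("%d-01-01", yr))
    }
    dplyr::bind_cols(tibble::tibble(year = yr),
                     max_sst_p90(series, ref, min_days = min_days, prob = prob))
  })
}
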