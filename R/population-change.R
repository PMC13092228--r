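#' Inclusion filter for per-taxon population analysis
#'
#' Retains taxa with at least `min_individuals` individuals across the entire
#' dataset and occurring in at least `min_plots` separate plots (defaults 20
#' and 5; both bounds inclusive). Rare or narrowly distributed taxa carry too
#' little information for per-taxon change estimates.
#'
#' @param matrix Site-year matrix ([pool_site_year_matrix()]).
#' @param plot_occupancy Named integer vector: number of distinct plots each
#'   taxon occurred in over the full dataset. Can be computed from raw records
#'   with [plot_occupancy_from_records()].
#' @param min_individuals,min_plots Inclusion thresholds.
#' @return A list: `taxa` (retained taxon names), `report` (tibble of removed
#'   taxa with totals, plots and reason) and `fraction_individuals_retained`.
#' @export
apply_inclusion_filter <- function(matrix, plot_occupancy,
                                   min_individuals = 20, min_plots = 5) {
  taxa <- setdiff(names(matrix), "year")
  totals <- colSums(matrix[, taxa, drop = FALSE])
  plots <- plot_occupancy[taxa]
  plots[is.na(plots)] <- 0L
  enough_n <- totals >= min_individuals
  enough_p <- plots >= min_plots
  keep <- enough_n & enough_p
  report <- tibble::tibble(
    taxon = taxa[!keep],
    total_individuals = unname(totals[!keep]),
    n_plots = unname(plots[!keep]),
    reason = dplyr::case_when(
      !enough_n[!keep] & !enough_p[!keep] ~ "too_few_individuals_and_plots",
      !enough_n[!keep] ~ "too_few_individuals",
      TRUE ~ "too_few_plots"
    )
  )
  list(
    taxa = taxa[keep],
    report = report,
    fraction_individuals_retained = sum(totals[keep]) / sum(totals)
  )
}

#' Plot occupancy from raw records
#'
#' Number of distinct plots (quadrats) in which each taxon was ever counted.
#'
#' @param records Counted record tibble.
#' @return Named integer vector, taxon -> number of plots.
#' @export
plot_occupancy_from_records <- function(records) {
  occ <- records |>
    dplyr::filter(!is.na(.data$count), .data$count > 0) |>
    dplyr::distinct(.data$taxon, .data$quadrat_id) |>
    dplyr::count(.data$taxon)
  setNames(occ$n, occ$taxon)
}

#' Per-taxon log response ratios against the historical baseline
#'
#' For each taxon, the log change in pooled site-level abundance for each
#' recent year relative to the baseline:
#' `lrr = ln((n_year + 1) / (n_baseline + 1))`, with the +1 offsets making
#' zeros well-defined. The mean over recent years summarizes change; its 95%
#' CI uses the normal approximation `mean +/- 1.96 se` by default
#' (`se = sd / sqrt(n_years)`) or a nonparametric bootstrap over years.
#'
#' @param matrix Site-year matrix.
#' @param baseline_year Label of the pooled baseline row.
#' @param recent_years Labels of the recent years (default: all other rows).
#' @param taxa Optional subset of taxa (e.g. from [apply_inclusion_filter()]).
#' @param ci_method `"normal"` (default) or `"bootstrap"`.
#' @param n_boot,seed Bootstrap settings when `ci_method = "bootstrap"`.
#' @return Tibble: `taxon`, `n_baseline`, `mean_lrr`, `se`, `ci_low`,
#'   `ci_high`, `n_years`, plus a nested `per_year` list-column of the yearly
#'   ratios.
#' @export
compute_lrr <- function(matrix, baseline_year = "1931-1933",
                        recent_years = NULL, taxa = NULL,
                        ci_method = c("normal", "bootstrap"),
                        n_boot = 2000, seed = 1) {
  ci_method <- match.arg(ci_method)
  if (!(baseline_year %in% matrix$year)) {
    abort(sprintf("Baseline label '%s' not present in the matrix.", baseline_year))
  }
  recent_years <- recent_years %||% setdiff(matrix$year, baseline_year)
  if (length(recent_years) == 0) abort("No recent years to compare against the baseline.")
  taxa <- taxa %||% setdiff(names(matrix), "year")
  base <- matrix[matrix$year == baseline_year, taxa, drop = FALSE]
  rec <- matrix[matrix$year %in% recent_years, taxa, drop = FALSE]
  purrr::map_dfr(taxa, function(tx) {
    n0 <- base[[tx]]
    lrr <- log((rec[[tx]] + 1) / (n0 + 1))
    m <- mean(lrr)
    k <- length(lrr)
    se <- if (k > 1) sd(lrr) / sqrt(k) else 0
    if (ci_method == "normal") {
      ci <- m + c(-1.96, 1.96) * se
    } else {
      ci <- local_seed(seed, {
        bm <- replicate(n_boot, mean(sample(lrr, k, replace = TRUE)))
        unname(quantile(bm, c(0.025, 0.975)))
      })
    }
    tibble::tibble(
      taxon = tx, n_baseline = n0, mean_lrr = m, se = se,
      ci_low = ci[1], ci_high = ci[2], n_years = k,
      per_year = list(tibble::tibble(year = matrix$year[matrix$year %in% recent_years],
                                     lrr = lrr))
    )
  })
}

#' Assign a geographic range category
#'
#' Classifies a taxon by its latitudinal range limits relative to two
#' biogeographic breakpoints on the northeast Pacific coast: a taxon whose
#' northern limit lies south of Cape Mendocino is "southern"; one whose
#' southern limit lies north of Point Conception is "northern"; one whose
#' range extends beyond both points is "coastwide"; otherwise "uncertain".
#'
#' @param northern_limit_lat,southern_limit_lat Range limits in degrees N
#'   (`NA` when unknown).
#' @param cape_mendocino_lat,point_conception_lat Breakpoint latitudes
#'   (defaults 40.44 and 34.45 degrees N).
#' @return One of `"southern"`, `"northern"`, `"coastwide"`, `"uncertain"`
#'   (vectorized over the limits).
#' @export
#' @examples
#' assign_range_category(northern_limit_lat = 38, southern_limit_lat = 30)
assign_range_category <- function(northern_limit_lat, southern_limit_lat,
                                  cape_mendocino_lat = 40.44,
                                  point_conception_lat = 34.45) {
  n <- max(length(northern_limit_lat), length(southern_limit_lat))
  nl <- rep_len(northern_limit_lat, n)
  sl <- rep_len(southern_limit_lat, n)
  bad <- !is.na(nl) & !is.na(sl) & nl < sl
  if (any(bad)) abort("Northern range limit below southern range limit.")
  is_south <- !is.na(nl) & nl < cape_mendocino_lat
  is_north <- !is.na(sl) & sl > point_conception_lat
  both <- is_south & is_north
  if (any(both)) {
    abort("Contradictory classification: limits satisfy both the southern and northern rule.")
  }
  coast <- !is.na(nl) & !is.na(sl) & nl >= cape_mendocino_lat & sl <= point_conception_lat
  out <- rep("uncertain", n)
  out[is_south] <- "southern"
  out[is_north] <- "northern"
  out[coast] <- "coastwide"
  out
}

#' Prepare the range contrast inputs for the measurement-error model
#'
#' Converts LRR records into the per-taxon observations the hierarchical
#' measurement-error model consumes: mean log change, its standard error
#' (floored at `se_floor` to avoid zero-variance degeneracy) and range class.
#' Uncertain-class taxa are retained in the output but flagged out of the
#' contrast.
#'
#' @param records LRR tibble with `taxon`, `mean_lrr`, `se` plus a
#'   `range_class` column.
#' @param se_floor Minimum standard error (default 1e-3).
#' @return Tibble: `taxon`, `obs_mean`, `se`, `range_class`,
#'   `in_contrast` (logical), `se_floored` (logical).
#' @export
range_contrast_inputs <- function(records, se_floor = 1e-3) {
  if (nrow(records) == 0) abort("Empty LRR input.")
  stopifnot(all(c("taxon", "mean_lrr", "se", "range_class") %in% names(records)))
  out <- tibble::tibble(
    taxon = records$taxon,
    obs_mean = records$mean_lrr,
    se = pmax(records$se, se_floor),
    range_class = records$range_class,
    in_contrast = records$range_class %in% c("southern", "coastwide"),
    se_floored = records$se < se_floor
  )
  counts <- table(out$range_class[out$in_contrast])
  for (cl in c("southern", "coastwide")) {
    if (is.na(counts[cl]) || counts[cl] < 2) {
      abort(sprintf("Range class '%s' has fewer than 2 taxa; the contrast is not estimable.", cl))
    }
  }
  out
}
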