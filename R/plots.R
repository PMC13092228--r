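#' Plot a coverage-standardized diversity time series
#'
#' One panel per metric, with the pooled baseline highlighted and bootstrap
#' intervals as ribbons.
#'
#' @param object A `shore_diversity_series` from [diversity_time_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot shore_diversity_series
autoplot.shore_diversity_series <- function(object, ...) {
  d <- object |>
    dplyr::mutate(
      is_baseline = is.na(suppressWarnings(as.numeric(.data$year))),
      year_num = suppressWarnings(as.numeric(.data$year))
    )
  base <- d[d$is_baseline, ]
  rec <- d[!d$is_baseline, ]
  p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$year_num, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Coverage-standardized estimate")
  if (nrow(base) > 0) {
    p <- p + ggplot2::geom_hline(data = base,
                                 ggplot2::aes(yintercept = .data$estimate),
                                 linetype = "dashed", na.rm = TRUE)
  }
  p
}

#' Plot posterior intervals of a fitted model
#'
#' Point (posterior median), 80% (thick) and 95% (thin) credible intervals
#' for every parameter of a `shore_fit`.
#'
#' @param object A `shore_fit`.
#' @param pars Optional subset of parameter names.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot shore_fit
autoplot.shore_fit <- function(object, pars = NULL, ...) {
  td <- tidy(object)
  if (!is.null(pars)) td <- td[td$term %in% pars, ]
  td <- td[!grepl("^(f|theta)\\[", td$term), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
                            linewidth = 0.4) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$conf.low.80, xmax = .data$conf.high.80),
                            linewidth = 1.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Posterior", y = NULL)
}

#' Plot per-taxon log response ratios
#'
#' Taxa ordered by mean log change relative to the historical baseline, with
#' 95% confidence intervals, coloured by geographic range class when present.
#'
#' @param lrr LRR tibble from [compute_lrr()] (optionally with a
#'   `range_class` column).
#' @return A ggplot object.
#' @export
plot_lrr <- function(lrr) {
  d <- dplyr::arrange(lrr, .data$mean_lrr)
  d$taxon <- factor(d$taxon, levels = d$taxon)
  aes <- if ("range_class" %in% names(d)) {
    ggplot2::aes(x = .data$mean_lrr, y = .data$taxon, colour = .data$range_class)
  } else {
    ggplot2::aes(x = .data$mean_lrr, y = .data$taxon)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Log response ratio vs. baseline", y = NULL,
                  colour = "Range")
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
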