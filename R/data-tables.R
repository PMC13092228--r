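#' Published per-taxon change summary for the historical transect
#'
#' The published summary of the 48 common taxa on the Hewatt-Sagarin
#' transect (Hopkins Marine Station, central California): per-taxon log
#' response ratio over 1993-2023 relative to the 1931-1933 baseline with its
#' 95% confidence interval, and the geographic range class (37 coastwide, 9
#' southern, 2 uncertain). Values are as printed (one decimal place), which
#' is why [count_strong_changes()] reports a rounding-aware convention
#' alongside the strict one. Used as the worked-example input for the
#' evidence bookkeeping.
#'
#' @return Tibble: `group`, `taxon`, `common_name`, `range_class`, `lrr`,
#'   `ci_low`, `ci_high`.
#' @export
#' @examples
#' tab <- transect_change_table()
#' count_strong_changes(tab)
transect_change_table <- function() {
  readr::read_csv(
    system.file("extdata", "hewatt_transect_lrr.csv", package = "shoretrends"),
    show_col_types = FALSE
  )
}
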