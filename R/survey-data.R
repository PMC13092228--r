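#' Investigator eras of the long-term transect
#'
#' The five analyzed investigator eras of the nine-decade survey: the
#' historical baseline and four recent eras. The 1949 resurvey covered only a
#' subset of the core quadrats and is rejected at load time.
#'
#' @return A tibble with `era_id`, `year_start`, `year_end`.
#' @export
era_table <- function() {
  tibble::tibble(
    era_id = c("1931-1933", "1993-1996", "1999-2015", "2016-2019", "2020-2023"),
    year_start = c(1931L, 1993L, 1999L, 2016L, 2020L),
    year_end = c(1933L, 1996L, 2015L, 2019L, 2023L)
  )
}

#' Core quadrat identifiers
#'
#' The 19 permanent ("core") quadrats resurveyed in every analyzed site-year:
#' quadrats 27-38 and 62-68 of the original transect.
#'
#' @return Character vector of quadrat identifiers.
#' @export
core_quadrats <- function() as.character(c(27:38, 62:68))

qualitative_codes <- c("abundant", "common", "occasional", "rare")

#' Map calendar years to investigator eras
#'
#' @param year Integer vector of calendar years.
#' @param eras Era definition table, see [era_table()].
#' @return Character vector of era labels (`NA` outside every era).
#' @export
era_for_year <- function(year, eras = era_table()) {
  idx <- vapply(year, function(y) {
    w <- which(y >= eras$year_start & y <= eras$year_end)
    if (length(w) == 1) w else NA_integer_
  }, integer(1))
  eras$era_id[idx]
}

#' Load raw survey records
#'
#' Reads a CSV of raw survey observations into validated survey records. Each
#' record is one taxon in one quadrat in one year, carrying either an integer
#' count or one of the qualitative abundance codes ("abundant", "common",
#' "occasional", "rare") used by the historical surveys -- never both.
#'
#' @param path CSV file path, or a data frame already in memory.
#' @param schema Named character vector mapping the canonical column names
#'   (`year`, `quadrat_id`, `taxon`, `count`, `qualitative_code`, optionally
#'   `date`) to the columns of the file. Defaults to identity.
#' @param quadrat_set Allowed quadrat identifiers (default [core_quadrats()]
#'   plus the "extra" quadrats added in 2020).
#' @param eras Era definition table, see [era_table()].
#' @return A tibble of records with columns `era_id`, `year`, `quadrat_id`,
#'   `taxon`, `count`, `qualitative_code` (and `date` if mapped). Rows from
#'   years outside the analyzed eras (e.g. the 1949 partial resurvey) are
#'   dropped with a warning.
#' @export
load_survey_records <- function(path, schema = NULL,
                                quadrat_set = c(core_quadrats(), "12", "16", "20", "24"),
                                eras = era_table()) {
  raw <- if (is.data.frame(path)) tibble::as_tibble(path) else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  canon <- c("year", "quadrat_id", "taxon", "count", "qualitative_code", "date")
  schema <- schema %||% setNames(canon, canon)
  needed <- c("year", "quadrat_id", "taxon")
  missing_cols <- setdiff(unname(schema[needed]), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required columns: ", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(
    year = as.integer(raw[[schema[["year"]]]]),
    quadrat_id = as.character(raw[[schema[["quadrat_id"]]]]),
    taxon = as.character(raw[[schema[["taxon"]]]])
  )
  out$count <- if (!is.na(schema["count"]) && schema[["count"]] %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[schema[["count"]]]]))
  } else NA_real_
  out$qualitative_code <- if (!is.na(schema["qualitative_code"]) &&
                              schema[["qualitative_code"]] %in% names(raw)) {
    code <- as.character(raw[[schema[["qualitative_code"]]]])
    code[!is.na(code) & code == ""] <- NA_character_
    code
  } else NA_character_
  if ("date" %in% names(schema) && schema[["date"]] %in% names(raw)) {
    out$date <- as.Date(raw[[schema[["date"]]]])
  }

  bad_both <- which(!is.na(out$count) & !is.na(out$qualitative_code))
  if (length(bad_both) > 0) {
    abort(paste0("Rows with both a count and a qualitative code: ",
                 paste(head(bad_both, 10), collapse = ", ")))
  }
  bad_neither <- which(is.na(out$count) & is.na(out$qualitative_code))
  if (length(bad_neither) > 0) {
    abort(paste0("Rows with neither a count nor a qualitative code: ",
                 paste(head(bad_neither, 10), collapse = ", ")))
  }
  bad_count <- which(!is.na(out$count) & (out$count < 0 | abs(out$count - round(out$count)) > 1e-8))
  if (length(bad_count) > 0) {
    abort(paste0("Rows with invalid (negative or non-integer) counts: ",
                 paste(head(bad_count, 10), collapse = ", ")))
  }
  bad_code <- which(!is.na(out$qualitative_code) & !(out$qualitative_code %in% qualitative_codes))
  if (length(bad_code) > 0) {
    abort(paste0("Rows with unknown qualitative codes: ",
                 paste(head(bad_code, 10), collapse = ", ")))
  }
  bad_quad <- which(!(out$quadrat_id %in% quadrat_set))
  if (length(bad_quad) > 0) {
    abort(paste0("Rows with quadrat ids outside the configured set: ",
                 paste(head(bad_quad, 10), collapse = ", ")))
  }

  out$era_id <- era_for_year(out$year, eras)
  n_out <- sum(is.na(out$era_id))
  if (n_out > 0) {
    warn(sprintf(
      "%d record(s) from years outside the analyzed eras (e.g. the 1949 partial resurvey) dropped.",
      n_out
    ))
    out <- out[!is.na(out$era_id), ]
  }
  dplyr::relocate(out, "era_id")
}

#' Harmonize taxon names against a crosswalk
#'
#' Replaces each recorded name with its current (analysis) name using a
#' taxonomy crosswalk, e.g. the whelk recorded historically as
#' *Acanthina punctulata* becomes *Acanthinucella punctulata*. The mapping is
#' deterministic and many-to-one; counts recorded under synonyms pool under
#' one analysis taxon downstream.
#'
#' @param records Record tibble from [load_survey_records()].
#' @param crosswalk Tibble with columns `taxon_recorded`, `analysis_taxon`
#'   (and optionally `rank`, `mobility`, `epibiont_flag`,
#'   `on_hewatt_full_list`).
#' @param strict If `TRUE` (default) unknown recorded names are an error; if
#'   `FALSE` they pass through unchanged, flagged in the report.
#' @return The records with `taxon` replaced by the analysis name, plus an
#'   attribute `"harmonization_report"`: a tibble of names changed.
#' @export
harmonize_taxonomy <- function(records, crosswalk, strict = TRUE) {
  stopifnot(all(c("taxon_recorded", "analysis_taxon") %in% names(crosswalk)))
  if (anyDuplicated(crosswalk$taxon_recorded)) {
    abort("Crosswalk maps at least one recorded name to multiple analysis names.")
  }
  map <- setNames(crosswalk$analysis_taxon, crosswalk$taxon_recorded)
  unknown <- setdiff(unique(records$taxon), names(map))
  if (length(unknown) > 0 && strict) {
    abort(paste0("Recorded names missing from the crosswalk: ",
                 paste(head(unknown, 20), collapse = ", ")))
  }
  new <- unname(map[records$taxon])
  passthrough <- is.na(new)
  new[passthrough] <- records$taxon[passthrough]
  report <- tibble::tibble(
    taxon_recorded = records$taxon[records$taxon != new],
    analysis_taxon = new[records$taxon != new]
  ) |> dplyr::distinct()
  out <- records
  out$taxon <- new
  attr(out, "harmonization_report") <- report
  attr(out, "unmatched_taxa") <- unknown
  out
}

crosswalk_lookup <- function(crosswalk, col, default) {
  if (col %in% names(crosswalk)) {
    setNames(crosswalk[[col]], crosswalk$analysis_taxon)
  } else {
    setNames(rep(default, nrow(crosswalk)), crosswalk$analysis_taxon)
  }
}

#' Filter harmonized records for quantitative analysis
#'
#' Applies, in order, the four removal rules used to prepare the counted
#' dataset: (a) taxa whose abundance was only ever scored qualitatively;
#' (b) limpet epibionts not assessed in the baseline survey; (c) records at
#' taxonomic levels above genus; (d) genus-level records when two or more
#' species of that genus were counted anywhere in the dataset (to avoid
#' inflating diversity). Taxa first counted after the baseline are then
#' reconciled with the baseline full species list: taxa absent from that list
#' become explicit zeros in the baseline; taxa on the list are retained in a
#' presence-only registry (they cannot enter count-based estimators).
#'
#' @param records Harmonized record tibble (see [harmonize_taxonomy()]).
#' @param crosswalk Crosswalk tibble; columns `rank`
#'   (`species`/`genus`/`above_genus`), `epibiont_flag`,
#'   `on_hewatt_full_list` are used when present.
#' @param baseline_era Era label of the historical baseline.
#' @return A list with `records` (counted records retained for analysis),
#'   `report` (a tibble: step, records_removed, individuals_removed, reason),
#'   `baseline_zeros` (taxa treated as true zeros in the baseline) and
#'   `presence_only` (taxa on the baseline full list but never counted then).
#' @export
apply_quantitative_filters <- function(records, crosswalk,
                                       baseline_era = "1931-1933") {
  rank <- crosswalk_lookup(crosswalk, "rank", "species")
  epibiont <- crosswalk_lookup(crosswalk, "epibiont_flag", FALSE)
  on_list <- crosswalk_lookup(crosswalk, "on_hewatt_full_list", FALSE)
  genus_of <- if ("genus" %in% names(crosswalk)) {
    setNames(crosswalk$genus, crosswalk$analysis_taxon)
  } else {
    # first word of the analysis name
    setNames(vapply(strsplit(crosswalk$analysis_taxon, "\\s+"), `[[`, character(1), 1),
             crosswalk$analysis_taxon)
  }

  steps <- list()
  note <- function(df, removed, reason) {
    steps[[length(steps) + 1]] <<- tibble::tibble(
      step = length(steps) + 1L,
      reason = reason,
      records_removed = nrow(removed),
      individuals_removed = sum(removed$count, na.rm = TRUE)
    )
    df
  }

  # (a) taxa never counted anywhere: qualitative-only
  counted_taxa <- unique(records$taxon[!is.na(records$count)])
  qual_only <- !(records$taxon %in% counted_taxa)
  out <- note(records[!qual_only, ], records[qual_only, ], "qualitative_only_taxon")
  # remaining qualitative records of counted taxa carry no numbers either
  qual_rec <- is.na(out$count)
  out <- note(out[!qual_rec, ], out[qual_rec, ], "qualitative_record_of_counted_taxon")

  # (b) epibionts
  is_epi <- !is.na(epibiont[out$taxon]) & epibiont[out$taxon]
  out <- note(out[!is_epi, ], out[is_epi, ], "epibiont")

  # (c) above-genus records
  is_above <- !is.na(rank[out$taxon]) & rank[out$taxon] == "above_genus"
  out <- note(out[!is_above, ], out[is_above, ], "above_genus")

  # (d) genus-level records with >= 2 counted congeneric species, dataset-wide
  sp_taxa <- unique(out$taxon[!is.na(rank[out$taxon]) & rank[out$taxon] == "species"])
  sp_per_genus <- table(genus_of[sp_taxa])
  collapse_genera <- names(sp_per_genus)[sp_per_genus >= 2]
  is_genus_rec <- !is.na(rank[out$taxon]) & rank[out$taxon] == "genus" &
    out$taxon %in% collapse_genera
  out <- note(out[!is_genus_rec, ], out[is_genus_rec, ], "genus_with_multiple_species")

  # baseline reconciliation for taxa never counted in the baseline era
  base_taxa <- unique(out$taxon[out$era_id == baseline_era])
  recent_taxa <- setdiff(unique(out$taxon), base_taxa)
  known <- recent_taxa[recent_taxa %in% names(on_list)]
  presence_only <- known[on_list[known]]
  baseline_zeros <- setdiff(recent_taxa, presence_only)

  report <- dplyr::bind_rows(steps)
  if (nrow(out) == 0) warn("All records removed by the quantitative filters.")
  list(records = out, report = report,
       baseline_zeros = baseline_zeros, presence_only = presence_only)
}

#' Pool filtered records to a site-year abundance matrix
#'
#' Sums counts over quadrats within each site-year, restricted to a fixed
#' quadrat set so that effort (number of quadrats) is constant across years.
#' The historical baseline is pooled under a single year label.
#'
#' @param records Counted records (qualitative records removed).
#' @param quadrat_set Quadrat identifiers to retain (default the 19 core
#'   quadrats).
#' @param year_labels Optional function mapping `(era_id, year)` to the
#'   site-year label; the default pools the baseline era under its era label
#'   and labels recent years by calendar year.
#' @param sum_duplicates If `FALSE` (default) duplicate
#'   (year, quadrat, taxon) rows are an error -- they usually indicate a
#'   double entry; set `TRUE` to sum them deliberately.
#' @param baseline_era Era pooled under one label.
#' @return A site-year matrix: tibble with `year` (ordered labels) and one
#'   non-negative integer column per taxon.
#' @export
pool_site_year_matrix <- function(records, quadrat_set = core_quadrats(),
                                  sum_duplicates = FALSE,
                                  baseline_era = "1931-1933") {
  if (any(is.na(records$count))) {
    abort("Records still contain qualitative rows; run apply_quantitative_filters() first.")
  }
  keep <- records$quadrat_id %in% quadrat_set
  rec <- records[keep, ]
  dropped_years <- setdiff(unique(records$year), unique(rec$year))
  if (length(dropped_years) > 0) {
    warn(paste0("Years with no quadrat from the configured set dropped: ",
                paste(sort(dropped_years), collapse = ", ")))
  }
  rec$site_year <- ifelse(rec$era_id == baseline_era, baseline_era,
                          as.character(rec$year))
  dup <- rec |>
    dplyr::count(.data$site_year, .data$quadrat_id, .data$taxon) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0 && !sum_duplicates) {
    abort(paste0(
      "Duplicate (year, quadrat, taxon) entries found (possible double entry); ",
      "first few: ",
      paste(head(paste(dup$site_year, dup$quadrat_id, dup$taxon, sep = "/"), 5),
            collapse = ", "),
      ". Set sum_duplicates = TRUE to sum them deliberately."
    ))
  }
  wide <- rec |>
    dplyr::group_by(.data$site_year, .data$taxon) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "count",
                       values_fill = 0) |>
    dplyr::rename(year = "site_year") |>
    dplyr::arrange(.data$year)
  # order: baseline first, then numeric years
  lab <- wide$year
  ord <- order(ifelse(lab == baseline_era, -Inf, suppressWarnings(as.numeric(lab))))
  wide[ord, ]
}

#' Mean density by investigator era
#'
#' Converts the site-year matrix to per-area densities (individuals per square
#' metre over the pooled quadrat area) and averages within investigator era;
#' the between-year SD is reported where an era has temporal replication and
#' is absent (NA) for the single pooled baseline.
#'
#' @param matrix Site-year matrix from [pool_site_year_matrix()].
#' @param n_quadrats Number of quadrats pooled per site-year (default 19).
#' @param quadrat_area_m2 Area of one quadrat in square metres. The original
#'   quadrats are square yards, hence the 0.8361 default.
#' @param eras Era definition table.
#' @return A long tibble: `era_id`, `taxon`, `mean_density`, `sd_density`,
#'   `n_years`.
#' @export
summarize_density_by_era <- function(matrix, n_quadrats = 19,
                                     quadrat_area_m2 = 0.8361,
                                     eras = era_table()) {
  if (quadrat_area_m2 <= 0) abort("`quadrat_area_m2` must be positive.")
  area <- n_quadrats * quadrat_area_m2
  long <- tidyr::pivot_longer(matrix, -"year", names_to = "taxon",
                              values_to = "count")
  long$era_id <- ifelse(long$year %in% eras$era_id, long$year,
                        era_for_year(suppressWarnings(as.integer(long$year)), eras))
  long |>
    dplyr::mutate(density = .data$count / area) |>
    dplyr::group_by(.data$era_id, .data$taxon) |>
    dplyr::summarise(
      mean_density = mean(.data$density),
      sd_density = if (dplyr::n() > 1) sd(.data$density) else NA_real_,
      n_years = dplyr::n(),
      .groups = "drop"
    )
}
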