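test_that("well-formed records load and validate", {
  rec <- load_survey_records(toy_records())
  expect_equal(nrow(rec), 5)
  expect_equal(rec$era_id[1], "1931-1933")
  expect_true(all(is.na(rec$qualitative_code)))

  # from an actual CSV with a schema mapping
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    dplyr::rename(toy_records(), yr = year, quad = quadrat_id, species = taxon),
    path
  )
  rec2 <- load_survey_records(path, schema = c(
    year = "yr", quadrat_id = "quad", taxon = "species",
    count = "count", qualitative_code = "qualitative_code"
  ))
  expect_equal(rec2$count, rec$count)
})

test_that("invalid records are rejected with informative errors", {
  bad <- toy_records()
  bad$count[2] <- -1
  expect_error(load_survey_records(bad), "2")

  both <- toy_records()
  both$qualitative_code[3] <- "rare"
  expect_error(load_survey_records(both), "both")

  missing_col <- toy_records()[, -4]
  missing_col$qualitative_code <- NULL
  expect_error(load_survey_records(missing_col), "neither")

  expect_error(
    load_survey_records(dplyr::mutate(toy_records(), quadrat_id = "999")),
    "quadrat"
  )
})

test_that("qualitative-only rows are valid records with absent count", {
  q <- toy_records()
  q$count[5] <- NA
  q$qualitative_code[5] <- "rare"
  rec <- load_survey_records(q)
  expect_true(is.na(rec$count[5]))
  expect_equal(rec$qualitative_code[5], "rare")
})

test_that("years outside the analyzed eras (1949) are dropped with a warning", {
  r <- toy_records()
  r$year[5] <- 1949L
  expect_warning(rec <- load_survey_records(r), "1949|outside")
  expect_equal(nrow(rec), 4)
})

test_that("taxonomy harmonization maps synonyms deterministically", {
  cw <- tibble::tibble(
    taxon_recorded = c("Acanthina punctulata", "Acanthinucella punctulata"),
    analysis_taxon = "Acanthinucella punctulata"
  )
  rec <- toy_records()[1:2, ]
  rec$taxon <- c("Acanthina punctulata", "Acanthinucella punctulata")
  out <- harmonize_taxonomy(rec, cw)
  expect_equal(unique(out$taxon), "Acanthinucella punctulata")
  rep <- attr(out, "harmonization_report")
  expect_equal(rep$taxon_recorded, "Acanthina punctulata")

  # unknown names: error in strict mode, flagged pass-through otherwise
  rec$taxon[1] <- "Mystery species"
  expect_error(harmonize_taxonomy(rec, cw), "Mystery")
  loose <- harmonize_taxonomy(rec, cw, strict = FALSE)
  expect_equal(loose$taxon[1], "Mystery species")
  expect_equal(attr(loose, "unmatched_taxa"), "Mystery species")
})

test_that("harmonization never increases the number of distinct taxa", {
  set.seed(5)
  for (i in 1:10) {
    names_in <- paste0("sp", sample(30, 15))
    cw <- tibble::tibble(
      taxon_recorded = unique(names_in),
      analysis_taxon = paste0("sp", sample(10, length(unique(names_in)), replace = TRUE))
    )
    rec <- toy_records()[rep(1, 15), ]
    rec$taxon <- names_in
    out <- harmonize_taxonomy(rec, cw)
    expect_lte(dplyr::n_distinct(out$taxon), dplyr::n_distinct(rec$taxon))
  }
})

filter_fixture <- function() {
  rec <- tibble::tibble(
    year = c(1993L, 1993L, 1993L, 1993L, 1994L, 1994L),
    quadrat_id = "27",
    taxon = c("Alpha one", "Beta", "Cladea", "Delta one",
              "Beta one", "Beta two"),
    count = c(5, 2, 9, NA, 3, 4),
    qualitative_code = c(NA, NA, NA, "rare", NA, NA),
    era_id = c(rep("1993-1996", 6))
  )
  cw <- tibble::tibble(
    taxon_recorded = c("Alpha one", "Beta", "Cladea", "Delta one", "Beta one", "Beta two"),
    analysis_taxon = taxon_recorded,
    rank = c("species", "genus", "above_genus", "species", "species", "species"),
    genus = c("Alpha", "Beta", "Cladea", "Delta", "Beta", "Beta"),
    epibiont_flag = FALSE,
    on_hewatt_full_list = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  list(rec = rec, cw = cw)
}

test_that("quantitative filters apply the four removal rules in order", {
  fx <- filter_fixture()
  out <- apply_quantitative_filters(fx$rec, fx$cw)
  # retained: Alpha one, Beta one, Beta two; removed: Delta one (qualitative
  # only), Cladea (above genus), Beta (genus with 2 counted congeners)
  expect_setequal(unique(out$records$taxon), c("Alpha one", "Beta one", "Beta two"))
  expect_equal(sum(out$report$records_removed), 3)
  removed <- out$report[out$report$records_removed > 0, ]
  expect_setequal(removed$reason,
                  c("qualitative_only_taxon", "above_genus", "genus_with_multiple_species"))
  expect_equal(sum(out$report$individuals_removed), 2 + 9)
})

test_that("a genus with exactly one counted congeneric species is retained", {
  fx <- filter_fixture()
  rec <- fx$rec[fx$rec$taxon != "Beta two", ]
  out <- apply_quantitative_filters(rec, fx$cw)
  expect_true("Beta" %in% out$records$taxon)
})

test_that("epibiont-flagged taxa are removed", {
  fx <- filter_fixture()
  fx$cw$epibiont_flag[fx$cw$analysis_taxon == "Alpha one"] <- TRUE
  out <- apply_quantitative_filters(fx$rec, fx$cw)
  expect_false("Alpha one" %in% out$records$taxon)
  expect_equal(out$report$individuals_removed[out$report$reason == "epibiont"], 5)
})

test_that("filtering is idempotent and clean data pass through unchanged", {
  fx <- filter_fixture()
  once <- apply_quantitative_filters(fx$rec, fx$cw)
  twice <- apply_quantitative_filters(once$records, fx$cw)
  expect_equal(twice$records, once$records)
  expect_equal(sum(twice$report$records_removed), 0)
})

test_that("baseline reconciliation splits zeros from presence-only taxa", {
  fx <- filter_fixture()
  fx$rec$year[1] <- 1931L
  fx$rec$era_id[1] <- "1931-1933"
  out <- apply_quantitative_filters(fx$rec, fx$cw)
  # Beta one/two first counted after the baseline and absent from the full
  # list -> true zeros; nothing on-list is missing from the baseline here
  expect_setequal(out$baseline_zeros, c("Beta one", "Beta two"))
  expect_length(out$presence_only, 0)
})

test_that("pooling sums counts over quadrats and fills zeros", {
  rec <- load_survey_records(toy_records())
  mat <- pool_site_year_matrix(rec)
  expect_equal(mat$`Tegula funebralis`[mat$year == "1931-1933"], 7)
  expect_equal(mat$`Tegula funebralis`[mat$year == "1993"], 5)
  expect_equal(mat$`Tegula brunnea`[mat$year == "1931-1933"], 0)
  # conservation: totals equal the sum of retained record counts
  expect_equal(sum(mat[, -1]), sum(rec$count))
})

test_that("pooling matches brute-force summation on a 19-quadrat toy", {
  set.seed(11)
  quads <- core_quadrats()
  grid <- expand.grid(year = c(2016L, 2017L), quadrat_id = quads,
                      taxon = c("A sp", "B sp"), stringsAsFactors = FALSE)
  grid$count <- rpois(nrow(grid), 3)
  grid$qualitative_code <- NA_character_
  rec <- load_survey_records(tibble::as_tibble(grid))
  mat <- pool_site_year_matrix(rec)
  for (yr in c("2016", "2017")) for (tx in c("A sp", "B sp")) {
    expect_equal(mat[[tx]][mat$year == yr],
                 sum(grid$count[grid$year == as.integer(yr) & grid$taxon == tx]))
  }
  expect_equal(rowSums(mat[, -1]), tapply(grid$count, grid$year, sum),
               ignore_attr = TRUE)
})

test_that("duplicate (year, quadrat, taxon) entries error unless summing is requested", {
  rec <- load_survey_records(toy_records())
  dup <- dplyr::bind_rows(rec, rec[3, ])
  expect_error(pool_site_year_matrix(dup), "Duplicate")
  mat <- pool_site_year_matrix(dup, sum_duplicates = TRUE)
  expect_equal(mat$`Tegula funebralis`[mat$year == "1993"], 10)
})

test_that("density summaries convert counts to per-square-metre rates", {
  mat <- tibble::tibble(year = c("1931-1933", "2016", "2017"),
                        `A sp` = c(76, 38, 38))
  dens <- summarize_density_by_era(mat)
  base <- dens[dens$era_id == "1931-1933", ]
  expect_equal(base$mean_density, 76 / (19 * 0.8361), tolerance = 1e-6)
  expect_true(is.na(base$sd_density)) # single pooled baseline: no replication
  rec_era <- dens[dens$era_id == "2016-2019", ]
  expect_equal(rec_era$sd_density, 0) # identical yearly totals
  expect_error(summarize_density_by_era(mat, quadrat_area_m2 = 0), "positive")
})
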