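#' One-command analysis pipeline
#'
#' Orchestrates the full analysis: ingest and validate raw records, harmonize
#' taxonomy, apply the quantitative filters, pool to the site-year matrix,
#' compute coverage-standardized diversity series, reduce the SST series to
#' the pre-survey maximum-temperature covariate, fit the requested Bayesian
#' models, grade the evidence, and compute per-taxon log response ratios with
#' the range-class contrast. Every stage is logged with row/taxon counts in a
#' run manifest so the filtering is auditable; identical inputs and seed
#' reproduce identical outputs.
#'
#' @param records Raw records: a CSV path or tibble (see
#'   [load_survey_records()]).
#' @param crosswalk Taxonomy crosswalk: CSV path or tibble.
#' @param traits Species traits (taxon, mobility, range limits): CSV path or
#'   tibble.
#' @param temperature Daily SST series: CSV path or tibble (`date`, `sst_c`).
#' @param metrics Diversity metrics for the time series.
#' @param attribution_metric The single metric carried into the attribution
#'   models (default Hill-Shannon, `"q1"`: it changes over time and is least
#'   sensitive to investigator era).
#' @param models Subset of `c("trend", "temp_naive", "temp_linear",
#'   "temp_gp", "lrr")` to fit.
#' @param baseline_era Label of the pooled historical baseline.
#' @param quadrat_set Quadrats defining constant effort (default: the core
#'   quadrats present in the data).
#' @param n_boot Bootstrap replicates for diversity CIs (0 for point
#'   estimates only).
#' @param seed Master seed for every stochastic stage.
#' @param mcmc Sampler settings shared by all fits (the GP model doubles the
#'   iterations internally when left at its own default).
#' @param out_dir Optional directory; when given, per-stage CSV/JSON outputs
#'   and the manifest are written there.
#' @param quiet Suppress stage messages.
#' @return A list: `matrix`, `diversity`, `covariates`, `fits` (named list of
#'   `shore_fit`s; `fits$trend` is the attribution metric's trend model),
#'   `evidence`, `lrr`, `manifest`.
#' @export
run_analysis <- function(records, crosswalk, traits = NULL, temperature = NULL,
                         metrics = c("q0", "q1", "q2", "evenness"),
                         attribution_metric = "q1",
                         models = c("trend", "temp_naive", "temp_linear",
                                    "temp_gp", "lrr"),
                         baseline_era = "1931-1933",
                         quadrat_set = NULL,
                         n_boot = 200, seed = 1,
                         mcmc = mcmc_control(seed = seed),
                         out_dir = NULL, quiet = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  stages <- list()
  log_stage <- function(stage, note, n_rows = NA_integer_) {
    stages[[length(stages) + 1]] <<- tibble::tibble(
      stage = stage, note = note, n_rows = as.integer(n_rows)
    )
  }
  read_input <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) {
      if (!file.exists(x)) abort(sprintf("Input file for %s not found: %s", what, x))
      readr::read_csv(x, show_col_types = FALSE)
    } else tibble::as_tibble(x)
  }
  input_digest <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      unname(tools::md5sum(x))
    } else if (requireNamespace("digest", quietly = TRUE)) {
      digest::digest(x)
    } else NA_character_
  }
  digests <- list(records = input_digest(records), crosswalk = input_digest(crosswalk),
                  traits = input_digest(traits), temperature = input_digest(temperature))

  # -- stage 1: ingest ----------------------------------------------------
  crosswalk_tbl <- read_input(crosswalk, "crosswalk")
  traits_tbl <- read_input(traits, "traits")
  temp_tbl <- read_input(temperature, "temperature")
  rec <- load_survey_records(if (is.character(records)) records else read_input(records, "records"))
  log_stage("ingest", "validated records", nrow(rec))
  say("ingest: %d records", nrow(rec))

  # -- stage 2: harmonize + filter ---------------------------------------
  rec <- harmonize_taxonomy(rec, crosswalk_tbl)
  filt <- apply_quantitative_filters(rec, crosswalk_tbl, baseline_era = baseline_era)
  log_stage("filter", paste0("removed ", sum(filt$report$records_removed), " records"),
            nrow(filt$records))
  say("filter: %d records retained", nrow(filt$records))

  # -- stage 3: pool ------------------------------------------------------
  quadrat_set <- quadrat_set %||% intersect(core_quadrats(), unique(filt$records$quadrat_id))
  mat <- pool_site_year_matrix(filt$records, quadrat_set = quadrat_set,
                               baseline_era = baseline_era)
  log_stage("pool", sprintf("%d site-years x %d taxa", nrow(mat), ncol(mat) - 1), nrow(mat))
  say("pool: %d site-years x %d taxa", nrow(mat), ncol(mat) - 1)

  # -- stage 4: diversity -------------------------------------------------
  div <- diversity_time_series(mat, metrics = metrics, n_boot = n_boot, seed = seed)
  log_stage("diversity", sprintf("coverage target %.4f", div$coverage[1]), nrow(div))
  say("diversity: standardized at coverage %.4f", div$coverage[1])

  recent <- div[div$year != baseline_era, ]
  baseline_vals <- div[div$year == baseline_era, ]
  trend_data_for <- function(metric) {
    d <- recent[recent$metric == metric & !is.na(recent$estimate), ]
    tibble::tibble(
      year = as.numeric(d$year),
      era = era_for_year(as.numeric(d$year)),
      y = d$estimate
    )
  }

  # -- stage 5: temperature covariate ------------------------------------
  covariates <- NULL
  if (!is.null(temp_tbl) && any(c("temp_naive", "temp_linear", "temp_gp") %in% models)) {
    yrs <- sort(unique(as.numeric(recent$year)))
    covariates <- covariates_for_surveys(temp_tbl, tibble::tibble(year = yrs))
    n_missing <- sum(is.na(covariates$t_max_p90))
    if (n_missing > 0) say("covariate: %d year(s) missing and excluded from attribution", n_missing)
    log_stage("covariate", sprintf("%d year(s) missing", n_missing), nrow(covariates))
  }

  # -- stage 6: model fits ------------------------------------------------
  fits <- list()
  if ("trend" %in% models) {
    fits$trend_by_metric <- lapply(setNames(metrics, metrics), function(m) {
      fit_trend_era_model(trend_data_for(m), mcmc = mcmc)
    })
    fits$trend <- fits$trend_by_metric[[attribution_metric]]
    log_stage("fit_trend", paste(metrics, collapse = ","), length(metrics))
  }
  if (!is.null(covariates)) {
    td <- trend_data_for(attribution_metric) |>
      dplyr::left_join(covariates[, c("year", "t_max_p90")], by = "year") |>
      dplyr::rename(t = "t_max_p90") |>
      dplyr::filter(!is.na(.data$t))
    if ("temp_naive" %in% models) {
      fits$temp_naive <- fit_temp_linear_model(td, mcmc = mcmc, naive = TRUE)
    }
    if ("temp_linear" %in% models) {
      fits$temp_linear <- fit_temp_linear_model(td, mcmc = mcmc)
    }
    if ("temp_gp" %in% models) {
      gp_mcmc <- mcmc_control(n_chains = mcmc$n_chains, n_iter = 2 * mcmc$n_iter,
                              n_warmup = 2 * mcmc$n_warmup, seed = mcmc$seed)
      fits$temp_gp <- fit_temp_gp_model(td, mcmc = gp_mcmc)
    }
    log_stage("fit_attribution", attribution_metric, nrow(td))
  }

  # -- stage 7: population change ----------------------------------------
  lrr_out <- NULL
  if ("lrr" %in% models) {
    occupancy <- plot_occupancy_from_records(filt$records)
    incl <- apply_inclusion_filter(mat, occupancy)
    lrr <- compute_lrr(mat, baseline_year = baseline_era, taxa = incl$taxa)
    if (!is.null(traits_tbl)) {
      lrr$range_class <- assign_range_category(
        traits_tbl$northern_limit_lat[match(lrr$taxon, traits_tbl$taxon)],
        traits_tbl$southern_limit_lat[match(lrr$taxon, traits_tbl$taxon)]
      )
      contrast <- range_contrast_inputs(lrr)
      fits$lrr_range <- fit_lrr_range_model(contrast[contrast$in_contrast, ], mcmc = mcmc)
    }
    lrr_out <- lrr
    log_stage("lrr", sprintf("%d taxa retained (%.1f%% of individuals)",
                             length(incl$taxa), 100 * incl$fraction_individuals_retained),
              length(incl$taxa))
    say("lrr: %d taxa retained", length(incl$taxa))
  }

  # -- stage 8: evidence --------------------------------------------------
  evidence <- list()
  if ("trend" %in% models) {
    evidence$trend <- purrr::map_dfr(metrics, function(m) {
      fit <- fits$trend_by_metric[[m]]
      p_neg <- mean(fit$draws$beta_year < 0)
      p_pos <- mean(fit$draws$beta_year > 0)
      dir <- if (p_neg >= p_pos) "negative" else "positive"
      p <- max(p_neg, p_pos)
      base <- baseline_vals$estimate[baseline_vals$metric == m]
      env <- if (length(base) == 1 && !is.na(base)) {
        pp <- suppressWarnings(
          posterior_predict(fit, sort(unique(fit$data$year)), seed = seed)
        )
        baseline_envelope_test(pp, base)
      } else NULL
      tibble::tibble(
        metric = m, direction = dir, p_sign = p,
        slope_grade = classify_slope_evidence(p),
        baseline_strong_change = if (is.null(env)) NA else env$strong_change,
        transition_year = if (is.null(env)) NA else as.numeric(env$transition_year)
      )
    })
  }
  for (nm in intersect(c("temp_naive", "temp_linear", "temp_gp"), names(fits))) {
    p <- fits[[nm]]$p_beta_temp_neg
    evidence[[nm]] <- tibble::tibble(
      subject = paste0(nm, ":beta_temp"), p_negative = p,
      grade = classify_slope_evidence(p)
    )
  }
  if (!is.null(lrr_out)) {
    evidence$population_changes <- count_strong_changes(lrr_out)
    if (!is.null(fits$lrr_range)) {
      evidence$range_contrast <- tibble::tibble(
        subject = "delta_southern_minus_coastwide",
        p_positive = fits$lrr_range$p_delta_pos,
        grade = classify_slope_evidence(fits$lrr_range$p_delta_pos)
      )
    }
  }
  log_stage("evidence", "graded", length(evidence))

  manifest <- list(
    package_version = as.character(utils::packageVersion("shoretrends")),
    seed = seed,
    mcmc = mcmc,
    metrics = metrics,
    attribution_metric = attribution_metric,
    models = models,
    input_digests = digests,
    stages = dplyr::bind_rows(stages)
  )

  result <- list(matrix = mat, diversity = div, covariates = covariates,
                 fits = fits, evidence = evidence, lrr = lrr_out,
                 filter_report = filt$report, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(mat, file.path(out_dir, "site_year_matrix.csv"))
    readr::write_csv(div, file.path(out_dir, "diversity_series.csv"))
    if (!is.null(covariates)) readr::write_csv(covariates, file.path(out_dir, "sst_covariates.csv"))
    if (!is.null(lrr_out)) {
      readr::write_csv(dplyr::select(lrr_out, -"per_year"), file.path(out_dir, "lrr.csv"))
    }
    jsonlite::write_json(
      list(evidence = evidence,
           manifest = c(manifest[c("package_version", "seed", "metrics",
                                   "attribution_metric", "models", "input_digests")],
                        list(stages = manifest$stages))),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE, na = "null"
    )
  }
  result
}
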