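#' Configuration for the synthetic survey generator
#'
#' The generator emulates the structure of the nine-decade transect dataset:
#' 19 quadrats pooled per site-year, a pooled historical baseline plus 17
#' recent site-years nested in 4 investigator eras, a lognormal species
#' abundance distribution whose taxa drift by geographic range class, a
#' temperature effect acting on the dominance structure (so warming lowers
#' Hill-Shannon diversity at fixed richness), era- and mobility-specific
#' detection effort (one era undercounts mobile taxa), negative-binomial
#' quadrat counts, and taxonomy quirks (synonyms, qualitative-only records,
#' genus-level records) injected at configured rates.
#'
#' @param seed Integer seed.
#' @param n_quadrats Quadrats per site-year (default 19).
#' @param recent_years Calendar years of the recent surveys (default 17 years
#'   spanning 1993-2023 in the 4 recent eras).
#' @param S_pool Species-pool size.
#' @param sad_meanlog,sad_sdlog Lognormal parameters of expected per-taxon
#'   site-year abundance.
#' @param sessile_abund_boost Log-units added to the expected abundance of
#'   sessile taxa. Sessile taxa on this shore are few but can be enormously
#'   abundant (barnacle-style recruitment pulses), while mobile taxa form
#'   the speciose rare tail; the default +2 encodes that structure.
#' @param prop_southern,prop_coastwide Range-class proportions (the remainder
#'   is "uncertain").
#' @param prop_mobile Proportion of mobile taxa.
#' @param trend_southern,trend_coastwide Log-abundance change per decade by
#'   range class.
#' @param beta_temp_true Dominance tilt per degree C: warm years shift
#'   abundance toward already-dominant taxa, lowering evenness and
#'   Hill-Shannon diversity without changing the species pool.
#' @param era_effort_mobile,era_effort_sessile Named detection probabilities
#'   per era; the default depresses mobile-taxon counts to 0.3 in the
#'   1999-2015 era, reproducing the observed era artifact.
#' @param era_overlook_scale_mobile Named per-era scale (individuals) of
#'   species-level overlooking for mobile taxa: in eras with scale `s > 0`,
#'   a mobile species whose thinned site total is `N` is dropped from that
#'   year's records entirely with probability `exp(-N/s)` (rare and cryptic
#'   species are the ones observers miss). `0` disables overlooking. Random
#'   count thinning alone produces an effort artifact that coverage
#'   standardization corrects, as it should; whole-species overlooking is
#'   the documented observer error that makes the richness artifact survive
#'   standardization. Default: scale 30 in the 1999-2015 era only.
#' @param dispersion Negative-binomial size per quadrat (clumping).
#' @param sst_mean_c,sst_seasonal_amp_c,sst_trend_c_per_yr,sst_noise_sd Daily
#'   SST model: mean, seasonal sinusoid amplitude, linear warming trend
#'   (default 0.01 degC per year) and daily noise SD.
#' @param synonym_rate,qualitative_rate,genus_rate Taxonomy quirk rates.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_quadrats = 19,
                       recent_years = c(1993, 1994, 1996,
                                        1999, 2002, 2005, 2009, 2014, 2015,
                                        2016:2019, 2020:2023),
                       S_pool = 120,
                       sad_meanlog = log(10), sad_sdlog = 1.5,
                       sessile_abund_boost = 2,
                       prop_southern = 0.2, prop_coastwide = 0.75,
                       prop_mobile = 0.7,
                       trend_southern = 0.15, trend_coastwide = -0.15,
                       beta_temp_true = 0.1,
                       era_effort_mobile = c("1931-1933" = 1, "1993-1996" = 1,
                                             "1999-2015" = 0.3, "2016-2019" = 1,
                                             "2020-2023" = 1),
                       era_effort_sessile = c("1931-1933" = 1, "1993-1996" = 1,
                                              "1999-2015" = 1, "2016-2019" = 1,
                                              "2020-2023" = 1),
                       era_overlook_scale_mobile = c("1931-1933" = 0,
                                                     "1993-1996" = 0,
                                                     "1999-2015" = 30,
                                                     "2016-2019" = 0,
                                                     "2020-2023" = 0),
                       dispersion = 1,
                       sst_mean_c = 12.5, sst_seasonal_amp_c = 1.5,
                       sst_trend_c_per_yr = 0.01, sst_noise_sd = 0.5,
                       synonym_rate = 0.1, qualitative_rate = 0.03,
                       genus_rate = 0.03) {
  cfg <- mget(names(formals(sim_config)))
  if (prop_southern + prop_coastwide > 1) {
    abort("Range-class proportions sum to more than 1.")
  }
  for (p in c(prop_southern, prop_coastwide, prop_mobile,
              synonym_rate, qualitative_rate, genus_rate,
              era_effort_mobile, era_effort_sessile)) {
    if (any(p < 0 | p > 1)) abort("Probabilities must be in [0, 1].")
  }
  if (dispersion <= 0) abort("`dispersion` must be positive.")
  eras <- era_table()$era_id
  if (!all(eras %in% names(era_effort_mobile)) ||
      !all(eras %in% names(era_effort_sessile)) ||
      !all(eras %in% names(era_overlook_scale_mobile))) {
    abort("Era effort must be specified for every era.")
  }
  if (any(era_overlook_scale_mobile < 0)) {
    abort("Overlooking scales must be non-negative.")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a daily sea-surface temperature series
#'
#' Seasonal sinusoid plus a linear warming trend plus daily noise, covering
#' the year before the earliest survey through the last survey year. With the
#' default 0.01 degC/yr trend, the annual 90th-percentile temperature warms
#' by about 0.3 degC over 30 years.
#'
#' @param config A [sim_config()].
#' @return Tibble `date`, `sst_c`.
#' @export
generate_temperature <- function(config) {
  first <- min(1931, min(config$recent_years)) - 1
  last <- max(config$recent_years)
  dates <- seq(as.Date(sprintf("%d-01-01", first)),
               as.Date(sprintf("%d-12-31", last)), by = "day")
  frac_year <- as.numeric(dates - dates[1]) / 365.25
  doy <- as.numeric(format(dates, "%j"))
  local_seed(config$seed + 101L, tibble::tibble(
    date = dates,
    sst_c = config$sst_mean_c +
      config$sst_seasonal_amp_c * sin(2 * pi * (doy - 105) / 365.25) +
      config$sst_trend_c_per_yr * frac_year +
      rnorm(length(dates), 0, config$sst_noise_sd)
  ))
}

sim_site_years <- function(config) {
  tibble::tibble(year = c(1931L, as.integer(config$recent_years))) |>
    dplyr::mutate(era_id = era_for_year(.data$year))
}

#' Generate a synthetic survey database
#'
#' Draws a community from the configured species-abundance model, observes it
#' through the era- and mobility-specific detection process, injects taxonomy
#' quirks, and returns both the raw records (as a field database would look)
#' and the full latent truth needed by recovery tests.
#'
#' @param config A [sim_config()].
#' @param temperature Optional pre-generated series from
#'   [generate_temperature()] (regenerated from the config when `NULL`).
#' @return A list:
#' \describe{
#'   \item{records}{raw survey records (year, quadrat_id, taxon, count or
#'     qualitative_code) including quirks}
#'   \item{crosswalk}{taxonomy crosswalk covering every emitted name}
#'   \item{traits}{taxon, mobility, range limits and true range class}
#'   \item{temperature}{the daily SST series used}
#'   \item{truth}{latent expected abundances, true/observed counts, the
#'     annual temperature covariate, quirk bookkeeping and the latent
#'     diversity estimands}
#' }
#' @export
generate_community <- function(config, temperature = NULL) {
  temperature <- temperature %||% generate_temperature(config)
  sy <- sim_site_years(config)
  n_y <- nrow(sy)
  S <- config$S_pool

  # pre-survey maximum-temperature covariate per site-year (p90 of the prior
  # calendar year, matching the analysis definition)
  tcov <- covariates_for_surveys(temperature, sy["year"], min_days = 200)
  Tvec <- tcov$t_max_p90
  Tc <- Tvec - mean(Tvec)

  local_seed(config$seed, {
    # --- taxa and traits -------------------------------------------------
    genus_id <- ceiling(seq_len(S) / 2)
    genus <- sprintf("Genus%03d", genus_id)
    taxon <- sprintf("%s species%03d", genus, seq_len(S))
    mobility <- ifelse(runif(S) < config$prop_mobile, "mobile", "sessile")
    u <- runif(S)
    range_class <- ifelse(u < config$prop_southern, "southern",
                   ifelse(u < config$prop_southern + config$prop_coastwide,
                          "coastwide", "uncertain"))
    northern_limit <- ifelse(range_class == "southern", runif(S, 35, 40.4),
                      ifelse(range_class == "coastwide", runif(S, 41, 55), NA))
    southern_limit <- ifelse(range_class == "coastwide", runif(S, 25, 34.4),
                      ifelse(range_class == "southern", runif(S, 24, 33), NA))

    # --- latent expected abundances -------------------------------------
    # sessile taxa: few species, high abundance (barnacle-style dominants);
    # mobile taxa: the speciose rare tail
    log_lambda0 <- rnorm(S, config$sad_meanlog, config$sad_sdlog) +
      ifelse(mobility == "sessile", config$sessile_abund_boost, 0)
    z <- as.numeric(scale(log_lambda0))         # dominance score
    trend <- dplyr::case_when(
      range_class == "southern" ~ config$trend_southern,
      range_class == "coastwide" ~ config$trend_coastwide,
      TRUE ~ 0
    )
    dec <- (sy$year - min(sy$year)) / 10
    log_lambda <- outer(log_lambda0, rep(1, n_y)) +
      outer(trend, dec) +
      config$beta_temp_true * outer(z, Tc)
    lambda <- exp(log_lambda)                    # S x n_y expected site totals

    # --- observation process --------------------------------------------
    quads <- core_quadrats()[seq_len(config$n_quadrats)]
    effort_for <- function(mob, era) {
      if (mob == "mobile") config$era_effort_mobile[[era]] else config$era_effort_sessile[[era]]
    }
    rec_list <- vector("list", n_y)
    true_counts <- obs_counts <- matrix(0L, S, n_y)
    for (t in seq_len(n_y)) {
      mu_q <- lambda[, t] / config$n_quadrats
      # quadrat-level NB counts, then coupled binomial thinning via qbinom so
      # that lowering effort can never increase a count under the same seed
      Nq <- matrix(rnbinom(S * config$n_quadrats, mu = rep(mu_q, config$n_quadrats),
                           size = config$dispersion), S, config$n_quadrats)
      Uq <- matrix(runif(S * config$n_quadrats), S, config$n_quadrats)
      eff <- vapply(seq_len(S), function(i) effort_for(mobility[i], sy$era_id[t]),
                    numeric(1))
      Oq <- matrix(0L, S, config$n_quadrats)
      for (qi in seq_len(config$n_quadrats)) {
        Oq[, qi] <- qbinom(Uq[, qi], Nq[, qi], eff)
      }
      # species-level overlooking of rare mobile taxa (the observer error
      # that survives coverage standardization); the uniforms are drawn
      # unconditionally so the RNG stream is identical across effort
      # configurations, and exp(-N/scale) is decreasing in N, so the coupled
      # decision is monotone: lowering effort can only add overlooking
      u_ol <- runif(S)
      scale_ol <- config$era_overlook_scale_mobile[[sy$era_id[t]]]
      if (scale_ol > 0) {
        overlooked <- mobility == "mobile" &
          u_ol < exp(-rowSums(Oq) / scale_ol)
        Oq[overlooked, ] <- 0L
      }
      true_counts[, t] <- rowSums(Nq)
      obs_counts[, t] <- rowSums(Oq)
      idx <- which(Oq > 0, arr.ind = TRUE)
      rec_list[[t]] <- tibble::tibble(
        year = sy$year[t],
        quadrat_id = quads[idx[, 2]],
        taxon = taxon[idx[, 1]],
        count = as.numeric(Oq[idx]),
        qualitative_code = NA_character_
      )
    }
    records <- dplyr::bind_rows(rec_list)

    # --- taxonomy quirks -------------------------------------------------
    syn_taxa <- taxon[runif(S) < config$synonym_rate]
    synonym_of <- setNames(paste0("Oldname ", sub(".* ", "", syn_taxa)), syn_taxa)
    base_syn <- records$year == 1931L & records$taxon %in% syn_taxa
    n_synonym_records <- sum(base_syn)
    records$taxon[base_syn] <- unname(synonym_of[records$taxon[base_syn]])

    n_qual_taxa <- round(config$qualitative_rate * S)
    qual_records <- if (n_qual_taxa > 0) {
      purrr::map_dfr(seq_len(n_qual_taxa), function(j) {
        tibble::tibble(
          year = 1931L,
          quadrat_id = sample(quads, 1 + rbinom(1, 3, 0.5)),
          taxon = sprintf("Qualonly species%02d", j),
          count = NA_real_,
          qualitative_code = sample(c("abundant", "common", "occasional", "rare"), 1)
        )
      })
    } else NULL

    genus_pool <- unique(genus[duplicated(genus_id) | duplicated(genus_id, fromLast = TRUE)])
    n_genus_taxa <- round(config$genus_rate * S)
    gen_quirk_genera <- head(genus_pool, n_genus_taxa)
    genus_records <- if (length(gen_quirk_genera) > 0) {
      purrr::map_dfr(gen_quirk_genera, function(g) {
        yrs <- sy$year[sy$year >= 2020]
        tibble::tibble(
          year = sample(yrs, 1),
          quadrat_id = sample(quads, 1),
          taxon = g,
          count = as.numeric(1 + rbinom(1, 5, 0.5)),
          qualitative_code = NA_character_
        )
      })
    } else NULL

    records <- dplyr::bind_rows(records, qual_records, genus_records)

    # --- crosswalk -------------------------------------------------------
    crosswalk <- dplyr::bind_rows(
      tibble::tibble(taxon_recorded = taxon, analysis_taxon = taxon,
                     rank = "species", genus = genus,
                     mobility = mobility, epibiont_flag = FALSE,
                     on_hewatt_full_list = TRUE),
      tibble::tibble(taxon_recorded = unname(synonym_of),
                     analysis_taxon = names(synonym_of),
                     rank = "species", genus = genus[match(names(synonym_of), taxon)],
                     mobility = mobility[match(names(synonym_of), taxon)],
                     epibiont_flag = FALSE, on_hewatt_full_list = TRUE),
      if (n_qual_taxa > 0) tibble::tibble(
        taxon_recorded = sprintf("Qualonly species%02d", seq_len(n_qual_taxa)),
        analysis_taxon = sprintf("Qualonly species%02d", seq_len(n_qual_taxa)),
        rank = "species", genus = "Qualonly",
        mobility = "mobile", epibiont_flag = FALSE, on_hewatt_full_list = FALSE),
      if (length(gen_quirk_genera) > 0) tibble::tibble(
        taxon_recorded = gen_quirk_genera, analysis_taxon = gen_quirk_genera,
        rank = "genus", genus = gen_quirk_genera,
        mobility = "mobile", epibiont_flag = FALSE, on_hewatt_full_list = FALSE)
    )

    traits <- tibble::tibble(
      taxon = taxon, mobility = mobility,
      northern_limit_lat = northern_limit, southern_limit_lat = southern_limit,
      range_class_true = range_class
    )

    # --- latent estimands ------------------------------------------------
    p_lat <- sweep(lambda, 2, colSums(lambda), "/")
    d1_latent <- exp(-colSums(p_lat * log(p_lat)))
    dec_c <- dec - mean(dec)
    fit_year <- stats::lm(d1_latent ~ dec_c)
    fit_temp <- stats::lm(d1_latent ~ dec_c + Tc)
    lrr_latent <- log((lambda[, -1, drop = FALSE] + 1) / (lambda[, 1] + 1))
    mean_lrr_latent <- rowMeans(lrr_latent)
    delta_latent <- mean(mean_lrr_latent[range_class == "southern"]) -
      mean(mean_lrr_latent[range_class == "coastwide"])

    truth <- list(
      site_years = sy,
      lambda = lambda,
      taxon = taxon,
      true_counts = true_counts,
      obs_counts = obs_counts,
      temperature_covariate = dplyr::bind_cols(sy, t_max_p90 = Tvec),
      beta_temp_true = config$beta_temp_true,
      era_effort_mobile = config$era_effort_mobile,
      era_effort_sessile = config$era_effort_sessile,
      range_class = setNames(range_class, taxon),
      quirk_counts = tibble::tibble(
        reason = c("synonym_records", "qualitative_only_records", "genus_level_records"),
        n_records = c(n_synonym_records,
                      if (is.null(qual_records)) 0L else nrow(qual_records),
                      if (is.null(genus_records)) 0L else nrow(genus_records)),
        n_individuals = c(NA_real_,
                          0,
                          if (is.null(genus_records)) 0 else sum(genus_records$count))
      ),
      estimands = tibble::tibble(
        parameter = c("beta_year_d1", "beta_temp_d1", "delta_lrr"),
        value = c(unname(stats::coef(fit_year)[2]),
                  unname(stats::coef(fit_temp)[3]),
                  delta_latent)
      ),
      d1_latent = d1_latent
    )

    list(records = records, crosswalk = crosswalk, traits = traits,
         temperature = temperature, truth = truth)
  })
}

#' End-to-end recovery suite on synthetic data
#'
#' Runs the full pipeline (ingest, harmonize, filter, pool, standardize,
#' covariate, fit) on `n_reps` independently generated synthetic databases
#' and reports bias, RMSE and empirical 95%-CI coverage of the decadal
#' Hill-Shannon trend, the temperature effect, and the southern-vs-coastwide
#' contrast, each judged against the latent (noise-free) estimand of its
#' replicate. Replicates whose fits fail convergence diagnostics are excluded
#' and counted.
#'
#' @param config A [sim_config()]; replicate r uses `seed + r`.
#' @param n_reps Number of replicates (>= 20 recommended for stable coverage).
#' @param mcmc Sampler settings (scaled-down default keeps the suite fast).
#' @return A list with `summary` (parameter, bias, rmse, coverage, n_used,
#'   n_failed_diagnostics) and `replicates` (per-replicate estimates).
#' @export
recovery_suite <- function(config = sim_config(), n_reps = 20,
                           mcmc = mcmc_control(n_chains = 2, n_iter = 1000,
                                               n_warmup = 500)) {
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- generate_community(cfg)
    res <- run_analysis(
      records = sim$records, crosswalk = sim$crosswalk, traits = sim$traits,
      temperature = sim$temperature, seed = cfg$seed, mcmc = mcmc,
      n_boot = 0, quiet = TRUE
    )
    truth <- setNames(sim$truth$estimands$value, sim$truth$estimands$parameter)
    grab <- function(fit, param, truth_val) {
      td <- tidy(fit)
      row <- td[td$term == param, ]
      tibble::tibble(
        parameter = param, estimate = row$estimate,
        ci_low = row$conf.low, ci_high = row$conf.high,
        truth = truth_val,
        covered = truth_val >= row$conf.low & truth_val <= row$conf.high,
        diagnostics_pass = isTRUE(fit$diagnostics_pass)
      )
    }
    dplyr::bind_rows(
      grab(res$fits$trend, "beta_year", truth[["beta_year_d1"]]),
      grab(res$fits$temp_linear, "beta_temp", truth[["beta_temp_d1"]]),
      grab(res$fits$lrr_range, "delta", truth[["delta_lrr"]])
    ) |> dplyr::mutate(rep = r, .before = 1)
  })
  summary <- reps |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = mean(.data$covered),
      n_used = dplyr::n(),
      n_failed_diagnostics = sum(!.data$diagnostics_pass),
      .groups = "drop"
    )
  list(summary = summary, replicates = reps)
}
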