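# Shared fixtures built in code.

# Fast sampler settings for tests that only need a correct posterior shape,
# not the full survey protocol.
test_mcmc <- function(seed = 1, n_chains = 2, n_iter = 1000, n_warmup = 500) {
  mcmc_control(n_chains = n_chains, n_iter = n_iter, n_warmup = n_warmup, seed = seed)
}

# The 17 recent survey years used throughout.
recent_years <- function() c(1993, 1994, 1996, 1999, 2002, 2005, 2009, 2014,
                             2015, 2016:2019, 2020:2023)

# A toy record set: counts in two quadrats across two eras.
toy_records <- function() {
  tibble::tibble(
    year = c(1931L, 1931L, 1993L, 1993L, 1993L),
    quadrat_id = c("27", "28", "27", "28", "27"),
    taxon = c("Tegula funebralis", "Tegula funebralis", "Tegula funebralis",
              "Tegula brunnea", "Tegula brunnea"),
    count = c(3, 4, 5, 2, 1),
    qualitative_code = NA_character_
  )
}

toy_crosswalk <- function() {
  tibble::tibble(
    taxon_recorded = c("Tegula funebralis", "Tegula brunnea", "Tegula mariana"),
    analysis_taxon = c("Tegula funebralis", "Tegula brunnea", "Tegula brunnea"),
    rank = "species",
    genus = "Tegula",
    mobility = "mobile",
    epibiont_flag = FALSE,
    on_hewatt_full_list = TRUE
  )
}

# Simulated trend data drawn from the Model-1 generative structure.
make_trend_data <- function(beta_year = -0.6, sigma = 0.4, alpha = 8,
                            seed = 1, beta_temp = NULL, t_fun = NULL) {
  yrs <- recent_years()
  withr::with_seed(seed, {
    yd <- (yrs - mean(yrs)) / 10
    t <- if (!is.null(t_fun)) t_fun(yrs) else 13 + rnorm(length(yrs), 0, 0.5)
    mu <- alpha + beta_year * yd
    if (!is.null(beta_temp)) mu <- mu + beta_temp * (t - mean(t))
    tibble::tibble(year = yrs, era = shoretrends::era_for_year(yrs),
                   t = t, y = mu + rnorm(length(yrs), 0, sigma))
  })
}

# Build a minimal shore_fit-shaped object from a matrix of draws per chain,
# for exercising the diagnostics in isolation.
fake_fit <- function(chains) {
  draws <- dplyr::bind_rows(lapply(seq_along(chains), function(ch) {
    d <- tibble::as_tibble(chains[[ch]])
    d$.chain <- ch
    d$.iteration <- seq_len(nrow(chains[[ch]]))
    d
  }))
  structure(list(model = "fake", draws = draws,
                 parameters = colnames(chains[[1]]),
                 mcmc = list(n_chains = length(chains))),
            class = "shore_fit")
}
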