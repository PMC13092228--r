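# Scaled-down sampler settings are used throughout: the conjugate Gibbs
# draws are nearly independent, so a few hundred retained draws resolve
# posterior medians and 95% bounds well enough for these checks.

test_that("the trend model is seed-deterministic and recovers a known slope", {
  d <- make_trend_data(beta_year = -0.6, sigma = 0.3, seed = 21)
  f1 <- suppressWarnings(fit_trend_era_model(d, mcmc = test_mcmc(seed = 2)))
  f2 <- suppressWarnings(fit_trend_era_model(d, mcmc = test_mcmc(seed = 2)))
  expect_identical(f1$draws, f2$draws)
  td <- tidy(f1)
  b <- td[td$term == "beta_year", ]
  expect_true(b$conf.low < -0.6 && -0.6 < b$conf.high)
  # draws bookkeeping: chains x (iter - warmup)
  expect_equal(nrow(f1$draws), 2 * 500)
})

test_that("a flat response gives a null slope and equal era intercepts", {
  d <- make_trend_data(beta_year = 0, sigma = 1e-3, alpha = 5, seed = 3)
  d$y <- 5 # exactly constant
  fit <- suppressWarnings(fit_trend_era_model(d, mcmc = test_mcmc(seed = 4)))
  td <- tidy(fit)
  b <- td[td$term == "beta_year", ]
  expect_lt(abs(b$estimate), 0.05)
  alphas <- td$estimate[grepl("^alpha", td$term)]
  expect_lt(max(alphas) - min(alphas), 0.05)
})

test_that("trend preconditions are enforced", {
  d <- make_trend_data()[1:4, ]
  expect_error(fit_trend_era_model(d), "6 years")
  d2 <- make_trend_data()
  d2$era <- d2$era[1]
  expect_error(fit_trend_era_model(d2), "2 eras")
})

test_that("a constant temperature leaves its coefficient at the prior", {
  d <- make_trend_data(seed = 5)
  d$t <- 13
  pr <- default_priors(d$y, d$t)
  fit <- suppressWarnings(fit_temp_linear_model(d, priors = pr, mcmc = test_mcmc(seed = 6)))
  td <- tidy(fit)
  b <- td[td$term == "beta_temp", ]
  # centered constant column is all zero: posterior == prior N(0, beta_temp_sd)
  expect_lt(abs(b$estimate), 0.35 * pr$beta_temp_sd)
  expect_equal(b$std.error, pr$beta_temp_sd, tolerance = 0.15)
})

test_that("temperature data without a temperature effect leave the year trend unchanged", {
  d <- make_trend_data(beta_year = -0.6, sigma = 0.3, seed = 7) # t is pure noise
  f1 <- suppressWarnings(fit_trend_era_model(d, mcmc = test_mcmc(seed = 8, n_iter = 2000, n_warmup = 500)))
  f2 <- suppressWarnings(fit_temp_linear_model(d, mcmc = test_mcmc(seed = 8, n_iter = 2000, n_warmup = 500)))
  b1 <- tidy(f1); b2 <- tidy(f2)
  m1 <- b1$estimate[b1$term == "beta_year"]
  m2 <- b2$estimate[b2$term == "beta_year"]
  mc_err <- 3 * (b1$std.error[b1$term == "beta_year"] / sqrt(1000) +
                 b2$std.error[b2$term == "beta_year"] / sqrt(1000)) + 0.05
  expect_lt(abs(m1 - m2), mc_err + 0.15)
  expect_error(fit_temp_linear_model(dplyr::select(d, -t)), "Temperature")
})

test_that("the naive variant drops year and era", {
  d <- make_trend_data(seed = 9)
  fit <- suppressWarnings(fit_temp_linear_model(d, mcmc = test_mcmc(seed = 10), naive = TRUE))
  expect_setequal(fit$parameters, c("alpha", "beta_temp", "sigma"))
  expect_true(fit$p_beta_temp_neg >= 0 && fit$p_beta_temp_neg <= 1)
})

test_that("the GP model collapses to the no-year linear model as eta -> 0", {
  d <- make_trend_data(beta_year = 0, beta_temp = -0.3, sigma = 0.3, seed = 11)
  pr <- default_priors(d$y, d$t)
  pr$eta_sd <- 1e-6 # pin the GP prior near zero
  gp <- suppressWarnings(fit_temp_gp_model(d, priors = pr, mcmc = test_mcmc(seed = 12)))
  lin <- suppressWarnings(fit_temp_linear_model(d, mcmc = test_mcmc(seed = 12), naive = TRUE))
  bg <- tidy(gp); bl <- tidy(lin)
  expect_lt(abs(bg$estimate[bg$term == "beta_temp"] -
                bl$estimate[bl$term == "beta_temp"]), 0.1)
  expect_lt(max(abs(gp$draws$eta)), 1e-4)
})

test_that("duplicate years are handled by the jitter", {
  d <- make_trend_data(seed = 13)
  d$year[2] <- d$year[1] # exact duplicate distance
  fit <- suppressWarnings(fit_temp_gp_model(d, mcmc = test_mcmc(seed = 14, n_iter = 400, n_warmup = 200)))
  expect_s3_class(fit, "shore_fit")
  expect_true(all(is.finite(fit$draws$beta_temp)))
})

test_that("GP preconditions are enforced", {
  d <- make_trend_data(seed = 15)[1:6, ]
  expect_error(fit_temp_gp_model(d), "8 years")
})

test_that("the measurement-error contrast model recovers a known difference", {
  set.seed(16)
  dd <- tibble::tibble(
    taxon = paste0("t", 1:40),
    obs_mean = c(rnorm(20, -1, 0.1), rnorm(20, 1, 0.1)),
    se = 0.1,
    range_class = rep(c("coastwide", "southern"), each = 20)
  )
  fit <- suppressWarnings(fit_lrr_range_model(dd, mcmc = test_mcmc(seed = 17)))
  td <- tidy(fit)
  delta <- td[td$term == "delta", ]
  expect_equal(delta$estimate, 2, tolerance = 0.15)
  expect_gt(fit$p_delta_pos, 0.99)

  # identical observations -> contrast centered at zero
  dd0 <- dd
  dd0$obs_mean <- 0.5
  f0 <- suppressWarnings(fit_lrr_range_model(dd0, mcmc = test_mcmc(seed = 18)))
  d0 <- tidy(f0)
  expect_lt(abs(d0$estimate[d0$term == "delta"]), 0.05)

  # enormous SEs: the contrast posterior falls back toward its prior width
  ddw <- dd
  ddw$se <- 100
  fw <- suppressWarnings(fit_lrr_range_model(ddw, mcmc = test_mcmc(seed = 19)))
  dw <- tidy(fw)
  expect_gt(dw$std.error[dw$term == "delta"],
            5 * delta$std.error)

  expect_error(fit_lrr_range_model(dd[c(1, 21, 22), ]), "fewer than 2")
})

test_that("rank-normalized diagnostics separate mixed from unmixed chains", {
  set.seed(20)
  good <- lapply(1:4, function(i) matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "x")))
  fit_good <- fake_fit(good)
  dg <- mcmc_diagnostics(fit_good, neff_min = 400)
  expect_lt(abs(dg$rhat - 1), 0.02)
  expect_true(dg$pass)
  # effective size of iid chains is close to the number of draws (cross-check
  # against coda on the pooled chains)
  expect_equal(dg$n_eff, 2000, tolerance = 0.25)
  co <- sum(sapply(good, function(m) coda::effectiveSize(m[, 1])))
  expect_equal(dg$n_eff, co, tolerance = 0.3)

  bad <- good
  bad[[1]] <- bad[[1]] + 10
  db <- mcmc_diagnostics(fake_fit(bad))
  expect_gt(db$rhat, 1.5)
  expect_false(db$pass)

  single <- fake_fit(good[1])
  ds <- mcmc_diagnostics(single)
  expect_true(is.na(ds$rhat))
})

test_that("posterior predictions envelope the mean and collapse without noise", {
  d <- make_trend_data(beta_year = -0.6, sigma = 0.4, seed = 22)
  fit <- suppressWarnings(fit_trend_era_model(d, mcmc = test_mcmc(seed = 23)))
  pp <- suppressWarnings(posterior_predict(fit, d$year, seed = 24))
  expect_true(all(pp$pi_low <= pp$mu_low + 1e-9))
  expect_true(all(pp$pi_high >= pp$mu_high - 1e-9))

  # noiseless limit: predictive interval collapses onto the mean interval
  fit0 <- fit
  fit0$draws$sigma <- 1e-12
  pp0 <- suppressWarnings(posterior_predict(fit0, d$year, seed = 25))
  expect_equal(pp0$pi_low, pp0$mu_low, tolerance = 1e-6)
  expect_equal(pp0$pi_high, pp0$mu_high, tolerance = 1e-6)

  # constant mean: identical intervals in every year
  fitc <- fit
  fitc$draws$beta_year <- 0
  for (a in grep("^alpha", names(fitc$draws), value = TRUE)) fitc$draws[[a]] <- 5
  ppc <- suppressWarnings(posterior_predict(fitc, d$year[1:3], seed = 26))
  expect_equal(ppc$mu_low, rep(ppc$mu_low[1], 3))

  expect_warning(posterior_predict(fit, 2100, seed = 27), "outside")
})

test_that("predictive intervals achieve near-nominal coverage of new data", {
  # one long-run check: simulate fresh observations from the same process and
  # count how many fall inside the 95% predictive interval at their year
  set.seed(28)
  hits <- 0; total <- 0
  d <- make_trend_data(beta_year = -0.4, sigma = 0.5, seed = 29)
  fit <- suppressWarnings(fit_trend_era_model(d, mcmc = test_mcmc(seed = 30)))
  pp <- suppressWarnings(posterior_predict(fit, d$year, seed = 31))
  for (r in 1:200) {
    ynew <- (8 - 0.4 * (d$year - mean(d$year)) / 10) + rnorm(nrow(d), 0, 0.5)
    hits <- hits + sum(ynew >= pp$pi_low & ynew <= pp$pi_high)
    total <- total + nrow(d)
  }
  expect_gt(hits / total, 0.90)
  expect_lte(hits / total, 1)
})

test_that("simulation-based calibration ranks are uniform for the fast models", {
  # Model 1 slope: draw the truth from its prior, simulate, fit, and rank the
  # truth within the posterior draws; ranks should be uniform
  set.seed(32)
  n_sims <- 40
  yrs <- recent_years()
  yd <- (yrs - mean(yrs)) / 10
  era <- era_for_year(yrs)
  n_bins <- 8
  ranks <- vapply(seq_len(n_sims), function(s) {
    b_true <- rnorm(1, 0, 0.5)
    a_true <- rnorm(4, 8, 0.5)[match(era, unique(era))] # one intercept per era
    sig <- rexp(1, 1 / 0.4)
    y <- a_true + b_true * yd + rnorm(length(yrs), 0, sig)
    pr <- list(alpha_mean = 8, alpha_sd = 0.5, beta_year_sd = 0.5,
               beta_temp_sd = 1, sigma_rate = 1 / 0.4,
               eta_sd = 1, ell_meanlog = log(8), ell_sdlog = 0.75)
    fit <- suppressWarnings(fit_trend_era_model(
      tibble::tibble(year = yrs, era = era, y = y), priors = pr,
      mcmc = test_mcmc(seed = 1000 + s, n_chains = 1, n_iter = 450, n_warmup = 100)
    ))
    draws <- fit$draws$beta_year[seq(1, 350, by = 50)] # thin toward independence
    sum(draws < b_true)
  }, numeric(1))
  tab <- tabulate(floor(ranks / 8 * n_bins) + 1, n_bins)
  chisq <- sum((tab - n_sims / n_bins)^2 / (n_sims / n_bins))
  expect_lt(chisq, qchisq(0.999, df = n_bins - 1))
})
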