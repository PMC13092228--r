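#' MCMC sampler settings
#'
#' Defaults mirror the survey analysis protocol: 4 chains of 3,000 iterations
#' with the first 1,500 discarded as warm-up, for 6,000 retained draws. The
#' Gaussian-process model doubles the iterations by default.
#'
#' @param n_chains Number of chains.
#' @param n_iter Iterations per chain (including warm-up).
#' @param n_warmup Warm-up iterations discarded per chain.
#' @param seed Integer seed; chains use `seed + chain`.
#' @return A list of sampler settings.
#' @export
mcmc_control <- function(n_chains = 4, n_iter = 3000, n_warmup = 1500, seed = 1) {
  stopifnot(n_warmup < n_iter, n_chains >= 1)
  list(n_chains = n_chains, n_iter = n_iter, n_warmup = n_warmup, seed = seed)
}

#' Weakly informative prior defaults
#'
#' Centered on the data scale: intercepts `N(mean(y), 2 sd(y))`, the decadal
#' slope `N(0, 2 sd(y))`, the temperature slope `N(0, 2 sd(y)/sd(t))`,
#' residual SD `Exponential(1/sd(y))`, GP marginal SD half-`N(0, sd(y))`, and
#' a lognormal length-scale prior spanning roughly 2-30 years.
#'
#' @param y Response vector.
#' @param t Optional temperature covariate (needed for `beta_temp`).
#' @return A list of prior hyperparameters.
#' @export
default_priors <- function(y, t = NULL) {
  s <- sd(y)
  if (!is.finite(s) || s == 0) s <- 1
  list(
    alpha_mean = mean(y), alpha_sd = 2 * s,
    beta_year_sd = 2 * s,
    beta_temp_sd = if (!is.null(t) && sd(t) > 0) 2 * s / sd(t) else 2 * s,
    sigma_rate = 1 / s,
    eta_sd = s,
    ell_meanlog = log(8), ell_sdlog = 0.75
  )
}

validate_trend_data <- function(data, need_t = FALSE) {
  stopifnot(is.data.frame(data), all(c("year", "y") %in% names(data)))
  if (need_t && (!"t" %in% names(data) || any(is.na(data$t)))) {
    abort("Temperature covariate `t` must be present (non-missing) for every retained year.")
  }
  if (any(is.na(data$y))) abort("Missing response values; drop those years first.")
  invisible(data)
}

center_year <- function(year, center = NULL) {
  center <- center %||% mean(year)
  list(year_c = (year - center) / 10, center = center)
}

new_shore_fit <- function(model, chains, data, priors, mcmc, extras = list()) {
  kept <- nrow(chains[[1]])
  draws <- dplyr::bind_rows(lapply(seq_along(chains), function(ch) {
    d <- tibble::as_tibble(chains[[ch]])
    d$.chain <- ch
    d$.iteration <- seq_len(kept)
    d
  }))
  fit <- structure(
    c(list(model = model, draws = draws, data = data, priors = priors,
           mcmc = mcmc, parameters = colnames(chains[[1]])), extras),
    class = "shore_fit"
  )
  # fit-time flag: the R-hat threshold is the protocol's 1.05; the effective
  # sample size bar is capped at a quarter of the retained draws so that
  # deliberately scaled-down runs are flagged for poor mixing, not for their
  # sample size (mcmc_diagnostics() itself keeps the full-protocol defaults)
  n_total <- kept * length(chains)
  fit$diagnostics <- mcmc_diagnostics(fit, rhat_max = 1.05,
                                      neff_min = min(1000, floor(n_total / 4)))
  fit$diagnostics_pass <- all(fit$diagnostics$pass, na.rm = TRUE)
  if (!fit$diagnostics_pass) {
    warn(sprintf("Fit '%s' failed convergence diagnostics; inspect mcmc_diagnostics().", model))
  }
  fit
}

draws_matrix_by_chain <- function(fit, parameter) {
  ch <- split(fit$draws[[parameter]], fit$draws$.chain)
  do.call(cbind, ch)
}

#' Trend-plus-era model for a diversity metric (Model 1)
#'
#' `y ~ Normal(alpha_era + beta_year * year_c, sigma)` where `year_c` is the
#' centered year in decades, so `beta_year` reads as change per decade.
#' Investigator era is an index (one intercept per era, no reference level):
#' eras are ordered in time and absorb observer differences without biasing
#' the trend.
#'
#' @param data Tibble with columns `year` (calendar year), `era` (label) and
#'   `y` (metric value), one row per site-year.
#' @param priors Prior list from [default_priors()] (computed from the data
#'   when `NULL`).
#' @param mcmc Sampler settings from [mcmc_control()].
#' @return A `shore_fit` object; see [tidy.shore_fit()], [mcmc_diagnostics()],
#'   [posterior_predict()].
#' @export
fit_trend_era_model <- function(data, priors = NULL, mcmc = mcmc_control()) {
  validate_trend_data(data)
  stopifnot("era" %in% names(data))
  if (length(unique(data$era)) < 2) abort("Need at least 2 eras.")
  if (length(unique(data$year)) < 6) abort("Need at least 6 years.")
  priors <- priors %||% default_priors(data$y)
  yc <- center_year(data$year)
  eras <- unique(data$era)
  X <- cbind(
    sapply(eras, function(e) as.numeric(data$era == e)),
    year_c = yc$year_c
  )
  colnames(X) <- c(paste0("alpha[", eras, "]"), "beta_year")
  chains <- gibbs_normal_lm(
    data$y, X,
    prior_mean = c(rep(priors$alpha_mean, length(eras)), 0),
    prior_sd = c(rep(priors$alpha_sd, length(eras)), priors$beta_year_sd),
    sigma_rate = priors$sigma_rate,
    n_chains = mcmc$n_chains, n_iter = mcmc$n_iter,
    n_warmup = mcmc$n_warmup, seed = mcmc$seed
  )
  new_shore_fit("trend_era", chains, data, priors, mcmc,
                extras = list(year_center = yc$center, eras = eras))
}

#' Linear temperature-attribution model (Model 2 and its naive variant)
#'
#' Estimates the effect of the pre-survey maximum-temperature covariate on a
#' diversity metric. The adjusted model
#' `y ~ Normal(alpha_era + beta_temp * t_c + beta_year * year_c, sigma)`
#' conditions on year (a fork: year is a common cause of both temperature and
#' diversity) so that `beta_temp` is a causal-effect estimate under the
#' study's graph. The naive variant (`naive = TRUE`) regresses on temperature
#' alone and is confounded by anything covarying with year; it exists as the
#' contrast that demonstrates the adjustment.
#'
#' @inheritParams fit_trend_era_model
#' @param data As in [fit_trend_era_model()], plus a complete `t` column
#'   (temperature, degrees C).
#' @param naive Drop year and era (confounded variant)?
#' @return A `shore_fit`; `fit$p_beta_temp_neg` holds the posterior
#'   probability of a negative temperature effect.
#' @export
fit_temp_linear_model <- function(data, priors = NULL, mcmc = mcmc_control(),
                                  naive = FALSE) {
  validate_trend_data(data, need_t = TRUE)
  priors <- priors %||% default_priors(data$y, data$t)
  tc <- data$t - mean(data$t)
  if (naive) {
    X <- cbind(alpha = 1, beta_temp = tc)
    prior_mean <- c(priors$alpha_mean, 0)
    prior_sd <- c(priors$alpha_sd, priors$beta_temp_sd)
    extras <- list(t_center = mean(data$t))
  } else {
    stopifnot("era" %in% names(data))
    yc <- center_year(data$year)
    eras <- unique(data$era)
    X <- cbind(
      sapply(eras, function(e) as.numeric(data$era == e)),
      beta_temp = tc, year_c = yc$year_c
    )
    colnames(X) <- c(paste0("alpha[", eras, "]"), "beta_temp", "beta_year")
    prior_mean <- c(rep(priors$alpha_mean, length(eras)), 0, 0)
    prior_sd <- c(rep(priors$alpha_sd, length(eras)),
                  priors$beta_temp_sd, priors$beta_year_sd)
    extras <- list(year_center = yc$center, t_center = mean(data$t), eras = eras)
  }
  chains <- gibbs_normal_lm(
    data$y, X, prior_mean, prior_sd, priors$sigma_rate,
    n_chains = mcmc$n_chains, n_iter = mcmc$n_iter,
    n_warmup = mcmc$n_warmup, seed = mcmc$seed
  )
  fit <- new_shore_fit(if (naive) "temp_naive" else "temp_linear",
                       chains, data, priors, mcmc, extras)
  fit$p_beta_temp_neg <- mean(fit$draws$beta_temp < 0)
  fit
}

#' Gaussian-process temperature-attribution model (Model 3)
#'
#' `y_i ~ Normal(alpha + beta_temp * t_c + f(year_i), sigma)` with
#' `f ~ GP(0, K)`, `K_ij = eta^2 exp(-d_ij^2 / (2 ell^2))` plus jitter on the
#' diagonal, where `d_ij` is the distance in years. The GP absorbs smooth,
#' autocorrelated confounds that covary with year (non-linear generalization
#' of the year adjustment), leaving `beta_temp` as the temperature effect.
#' The latent function is marginalized for sampling and its values `f[year]`
#' are drawn afterwards for each retained iteration.
#'
#' @inheritParams fit_temp_linear_model
#' @param mcmc Sampler settings; the default doubles the iterations relative
#'   to the linear models, as GP hyperparameters mix more slowly.
#' @param include_era Add era intercepts? Default `FALSE`: the GP over year
#'   can absorb era-block shifts.
#' @param jitter Diagonal jitter for numerical positive-definiteness (also
#'   what makes duplicate years well-posed).
#' @return A `shore_fit` with parameters `alpha`, `beta_temp`, `eta`, `ell`,
#'   `sigma`, latent `f[...]` columns, and `p_beta_temp_neg`.
#' @export
fit_temp_gp_model <- function(data, priors = NULL,
                              mcmc = mcmc_control(n_iter = 6000, n_warmup = 3000),
                              include_era = FALSE, jitter = 1e-6) {
  validate_trend_data(data, need_t = TRUE)
  if (length(unique(data$year)) < 8) abort("Need at least 8 years for the GP model.")
  priors <- priors %||% default_priors(data$y, data$t)
  n <- nrow(data)
  tc <- data$t - mean(data$t)
  d2 <- outer(data$year, data$year, "-")^2
  X <- if (include_era) {
    stopifnot("era" %in% names(data))
    eras <- unique(data$era)
    cbind(sapply(eras, function(e) as.numeric(data$era == e)), beta_temp = tc)
  } else {
    cbind(alpha = 1, beta_temp = tc)
  }
  if (include_era) colnames(X) <- c(paste0("alpha[", unique(data$era), "]"), "beta_temp")
  p <- ncol(X)
  prior_mean <- c(rep(priors$alpha_mean, p - 1), 0)
  prior_sd <- c(rep(priors$alpha_sd, p - 1), priors$beta_temp_sd)

  run_chain <- function(ch) local_seed(mcmc$seed + ch, {
    sy <- sd(data$y)
    beta <- prior_mean
    eta <- sy * exp(runif(1, -1, 0))
    ell <- exp(priors$ell_meanlog + priors$ell_sdlog * runif(1, -1, 1))
    sigma <- sy * exp(runif(1, -1, 0))
    kept <- matrix(NA_real_, mcmc$n_iter - mcmc$n_warmup, p + 3 + n)
    for (it in seq_len(mcmc$n_iter)) {
      K <- se_kernel(d2, ell)
      S <- eta^2 * K + diag(sigma^2 + jitter, n)
      U <- tryCatch(chol(S), error = function(e) {
        abort("Kernel matrix not positive definite; increase `jitter`.")
      })
      Sinv <- chol2inv(U)
      # conjugate (alpha, beta) under the marginal MVN
      prec <- t(X) %*% Sinv %*% X + diag(1 / prior_sd^2, p)
      b <- t(X) %*% Sinv %*% data$y + prior_mean / prior_sd^2
      Up <- chol(prec)
      mu <- backsolve(Up, forwardsolve(t(Up), b))
      beta <- drop(mu + backsolve(Up, rnorm(p)))
      r <- data$y - drop(X %*% beta)
      # slice updates for the covariance scales
      eta <- exp(slice_sample_1d(log(eta), function(le) {
        e <- exp(le)
        gp_marginal_loglik(r, K, e, sigma, jitter) + dnorm(e, 0, priors$eta_sd, log = TRUE) + le
      }, w = 0.5))
      ell <- exp(slice_sample_1d(log(ell), function(ll) {
        l2 <- exp(ll)
        gp_marginal_loglik(r, se_kernel(d2, l2), eta, sigma, jitter) +
          dnorm(ll, priors$ell_meanlog, priors$ell_sdlog, log = TRUE)
      }, w = 0.5))
      K <- se_kernel(d2, ell)
      sigma <- exp(slice_sample_1d(log(sigma), function(ls) {
        s <- exp(ls)
        gp_marginal_loglik(r, K, eta, s, jitter) - priors$sigma_rate * s + ls
      }, w = 0.5))
      if (it > mcmc$n_warmup) {
        # draw the latent f | rest
        Kf <- eta^2 * K
        S <- Kf + diag(sigma^2 + jitter, n)
        U <- chol(S)
        A <- backsolve(U, forwardsolve(t(U), Kf))      # S^-1 Kf
        f_mean <- drop(crossprod(A, r))
        f_cov <- Kf - crossprod(A, Kf)
        f_cov <- (f_cov + t(f_cov)) / 2
        ev <- eigen(f_cov, symmetric = TRUE)
        lam <- pmax(ev$values, 0)
        f <- drop(f_mean + ev$vectors %*% (sqrt(lam) * rnorm(n)))
        kept[it - mcmc$n_warmup, ] <- c(beta, eta, ell, sigma, f)
      }
    }
    colnames(kept) <- c(colnames(X), "eta", "ell", "sigma",
                        paste0("f[", seq_len(n), "]"))
    kept
  })
  chains <- lapply(seq_len(mcmc$n_chains), run_chain)
  fit <- new_shore_fit("temp_gp", chains, data, priors, mcmc,
                       extras = list(t_center = mean(data$t), jitter = jitter))
  fit$p_beta_temp_neg <- mean(fit$draws$beta_temp < 0)
  fit
}

#' Hierarchical measurement-error model for range-class contrasts (Model 4)
#'
#' Each taxon's observed mean log change is an error-prone measurement of an
#' unobserved true change: `obs_i ~ Normal(theta_i, se_i)` with
#' `theta_i ~ Normal(alpha_class(i), sigma_theta)`. The estimand is
#' `delta = alpha_southern - alpha_coastwide`, the difference in average true
#' log change between southern-range and coastwide taxa.
#'
#' @param data Tibble with `obs_mean`, `se`, `range_class` (only rows whose
#'   class is `southern` or `coastwide` enter; see
#'   [range_contrast_inputs()]).
#' @inheritParams fit_trend_era_model
#' @param mcmc Sampler settings (default 2,000 iterations, half warm-up, per
#'   the survey protocol for this model).
#' @return A `shore_fit` with `alpha_southern`, `alpha_coastwide`,
#'   `sigma_theta`, `delta`, per-taxon `theta[...]`, and `p_delta_pos`.
#' @export
fit_lrr_range_model <- function(data, priors = NULL,
                                mcmc = mcmc_control(n_iter = 2000, n_warmup = 1000)) {
  stopifnot(all(c("obs_mean", "se", "range_class") %in% names(data)))
  d <- data[data$range_class %in% c("southern", "coastwide"), ]
  counts <- table(d$range_class)
  for (cl in c("southern", "coastwide")) {
    if (is.na(counts[cl]) || counts[cl] < 2) {
      abort(sprintf("Range class '%s' has fewer than 2 taxa.", cl))
    }
  }
  if (any(d$se <= 0)) abort("Standard errors must be positive; apply the se floor first.")
  m <- nrow(d)
  cls <- ifelse(d$range_class == "southern", 1L, 2L)
  s <- sd(d$obs_mean)
  if (!is.finite(s) || s == 0) s <- 1
  priors <- priors %||% list(alpha_mean = mean(d$obs_mean), alpha_sd = 2 * s,
                             sigma_rate = 1 / s)
  run_chain <- function(ch) local_seed(mcmc$seed + ch, {
    alpha <- rep(priors$alpha_mean, 2) + 0.1 * s * rnorm(2)
    sigma_theta <- s * exp(runif(1, -1, 0))
    theta <- d$obs_mean
    kept <- matrix(NA_real_, mcmc$n_iter - mcmc$n_warmup, 3 + m)
    for (it in seq_len(mcmc$n_iter)) {
      prec <- 1 / d$se^2 + 1 / sigma_theta^2
      mu <- (d$obs_mean / d$se^2 + alpha[cls] / sigma_theta^2) / prec
      theta <- rnorm(m, mu, 1 / sqrt(prec))
      for (k in 1:2) {
        idx <- cls == k
        nk <- sum(idx)
        prec_a <- nk / sigma_theta^2 + 1 / priors$alpha_sd^2
        mu_a <- (sum(theta[idx]) / sigma_theta^2 + priors$alpha_mean / priors$alpha_sd^2) / prec_a
        alpha[k] <- rnorm(1, mu_a, 1 / sqrt(prec_a))
      }
      ssq <- sum((theta - alpha[cls])^2)
      sigma_theta <- exp(slice_sample_1d(log(sigma_theta), function(ls) {
        st <- exp(ls)
        -m * ls - ssq / (2 * st^2) - priors$sigma_rate * st + ls
      }, w = 0.5))
      if (it > mcmc$n_warmup) {
        kept[it - mcmc$n_warmup, ] <- c(alpha, sigma_theta, theta)
      }
    }
    colnames(kept) <- c("alpha_southern", "alpha_coastwide", "sigma_theta",
                        paste0("theta[", d$taxon %||% seq_len(m), "]"))
    kept
  })
  chains <- lapply(seq_len(mcmc$n_chains), run_chain)
  fit <- new_shore_fit("lrr_range", chains, d, priors, mcmc)
  fit$draws$delta <- fit$draws$alpha_southern - fit$draws$alpha_coastwide
  fit$parameters <- c(fit$parameters, "delta")
  fit$p_delta_pos <- mean(fit$draws$delta > 0)
  fit
}

#' Convergence diagnostics for a fit
#'
#' Rank-normalized split-chain potential scale reduction (R-hat) and
#' effective sample size for every free parameter, judged against the
#' protocol thresholds: R-hat strictly below `rhat_max` (default 1.05) and
#' effective sample size strictly above `neff_min` (default 1,000).
#'
#' @param fit A `shore_fit`.
#' @param rhat_max,neff_min Thresholds.
#' @return Tibble: `parameter`, `rhat`, `n_eff`, `pass`. With a single chain
#'   R-hat is undefined (`NA`) and cannot pass.
#' @export
mcmc_diagnostics <- function(fit, rhat_max = 1.05, neff_min = 1000) {
  params <- setdiff(fit$parameters, character(0))
  purrr::map_dfr(params, function(p) {
    mat <- draws_matrix_by_chain(fit, p)
    if (ncol(mat) < 2) {
      return(tibble::tibble(parameter = p, rhat = NA_real_,
                            n_eff = ess_rank_normalized(mat), pass = NA))
    }
    rh <- rhat_rank_normalized(mat)
    ne <- ess_rank_normalized(mat)
    tibble::tibble(parameter = p, rhat = rh, n_eff = ne,
                   pass = !is.na(rh) && rh < rhat_max && ne > neff_min)
  })
}

#' Posterior predictions over a year grid
#'
#' For each requested year, the 95% credible interval of the mean response
#' and the 95% posterior-predictive interval for a new observation (mean plus
#' residual noise). For the era model each prediction year inherits the era
#' of the nearest observed year.
#'
#' @param fit A `shore_fit` from [fit_trend_era_model()] or
#'   [fit_temp_linear_model()].
#' @param years Numeric vector of calendar years.
#' @param t Temperature values for the prediction years (required by the
#'   temperature models).
#' @param seed Seed for the predictive noise draws.
#' @param guard_years Warn when predicting more than this many years beyond
#'   the observed range (default 10).
#' @return Tibble: `year`, `mu_low`, `mu_high`, `pi_low`, `pi_high`.
#' @export
posterior_predict <- function(fit, years, t = NULL, seed = 1, guard_years = 10) {
  if (!isTRUE(fit$diagnostics_pass)) {
    warn("Fit failed convergence diagnostics; predictions may be unreliable.")
  }
  rng <- range(fit$data$year)
  if (any(years < rng[1] - guard_years | years > rng[2] + guard_years)) {
    warn("Some prediction years are far outside the observed range.")
  }
  draws <- fit$draws
  nd <- nrow(draws)
  mu_for_year <- function(yr, tt) {
    mu <- switch(fit$model,
      trend_era = {
        era <- fit$data$era[which.min(abs(fit$data$year - yr))]
        draws[[paste0("alpha[", era, "]")]] +
          draws$beta_year * (yr - fit$year_center) / 10
      },
      temp_linear = {
        era <- fit$data$era[which.min(abs(fit$data$year - yr))]
        draws[[paste0("alpha[", era, "]")]] +
          draws$beta_year * (yr - fit$year_center) / 10 +
          draws$beta_temp * (tt - fit$t_center)
      },
      temp_naive = draws$alpha + draws$beta_temp * (tt - fit$t_center),
      abort(sprintf("posterior_predict not implemented for model '%s'.", fit$model))
    )
    mu
  }
  local_seed(seed, purrr::map_dfr(seq_along(years), function(i) {
    tt <- if (!is.null(t)) t[i] else NA_real_
    mu <- mu_for_year(years[i], tt)
    ypred <- mu + rnorm(nd, 0, draws$sigma)
    tibble::tibble(
      year = years[i],
      mu_low = unname(quantile(mu, 0.025)), mu_high = unname(quantile(mu, 0.975)),
      pi_low = unname(quantile(ypred, 0.025)), pi_high = unname(quantile(ypred, 0.975))
    )
  }))
}

#' Prior predictive simulation for the trend model
#'
#' Draws regression parameters from the priors and simulates metric
#' trajectories, the standard check that the priors admit a wide range of
#' plausible temporal trends before seeing the data.
#'
#' @inheritParams fit_trend_era_model
#' @param n_sims Number of prior draws.
#' @param seed Seed.
#' @return Tibble: `sim`, `year`, `y_sim`.
#' @export
prior_predictive_trend <- function(data, priors = NULL, n_sims = 100, seed = 1) {
  validate_trend_data(data)
  priors <- priors %||% default_priors(data$y)
  yc <- center_year(data$year)
  local_seed(seed, purrr::map_dfr(seq_len(n_sims), function(s) {
    a <- rnorm(1, priors$alpha_mean, priors$alpha_sd)
    b <- rnorm(1, 0, priors$beta_year_sd)
    sig <- rexp(1, priors$sigma_rate)
    tibble::tibble(sim = s, year = data$year,
                   y_sim = rnorm(nrow(data), a + b * yc$year_c, sig))
  }))
}

#' @export
print.shore_fit <- function(x, ...) {
  cat(sprintf("<shore_fit: %s>\n", x$model))
  cat(sprintf("  %d chains x %d retained draws; diagnostics %s\n",
              x$mcmc$n_chains, x$mcmc$n_iter - x$mcmc$n_warmup,
              if (isTRUE(x$diagnostics_pass)) "passed" else "FAILED"))
  print(tidy(x), n = 12)
  invisible(x)
}

#' Tidy a shore_fit
#'
#' One row per model parameter with posterior median, SD, 95% and 80%
#' credible bounds, and the probability of a negative value.
#'
#' @param x A `shore_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy
#' @export
#' @method tidy shore_fit
tidy.shore_fit <- function(x, ...) {
  params <- x$parameters
  purrr::map_dfr(params, function(p) {
    d <- x$draws[[p]]
    q <- quantile(d, c(0.025, 0.1, 0.9, 0.975))
    tibble::tibble(
      term = p, estimate = median(d), std.error = sd(d),
      conf.low = q[[1]], conf.high = q[[4]],
      conf.low.80 = q[[2]], conf.high.80 = q[[3]],
      p_negative = mean(d < 0)
    )
  })
}

#' Glance at a shore_fit
#'
#' @param x A `shore_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, draw counts, worst R-hat, smallest
#'   effective sample size, and whether diagnostics passed.
#' @importFrom generics glance
#' @export
#' @method glance shore_fit
glance.shore_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_chains = x$mcmc$n_chains,
    n_draws = nrow(x$draws),
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    min_n_eff = suppressWarnings(min(x$diagnostics$n_eff, na.rm = TRUE)),
    diagnostics_pass = isTRUE(x$diagnostics_pass)
  )
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance
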