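#' Abundance summary statistics
#'
#' Summarize a vector of per-taxon counts into the quantities the
#' coverage-based estimators need: total individuals `n`, observed richness
#' `S_obs`, and the singleton/doubleton tallies `f1`, `f2`.
#'
#' @param x Non-negative integer vector of per-taxon counts.
#' @return A one-row tibble with columns `n`, `S_obs`, `f1`, `f2`.
#' @export
#' @examples
#' abundance_stats(c(4, 3, 2, 1))
abundance_stats <- function(x) {
  if (!is_count_vector(x)) abort("`x` must be a vector of non-negative integer counts.")
  x <- round(x)
  tibble::tibble(
    n = sum(x),
    S_obs = sum(x > 0),
    f1 = sum(x == 1),
    f2 = sum(x == 2)
  )
}

#' Hill number of order q
#'
#' The effective number of equally abundant taxa at sensitivity order `q`:
#' `q = 0` counts all taxa equally (richness), `q = 1` weights taxa by their
#' relative abundance (Hill-Shannon, the exponential of Shannon entropy), and
#' `q = 2` emphasizes dominant taxa (Hill-Simpson, inverse Simpson
#' concentration). All orders share the units "effective taxa" and are
#' directly comparable.
#'
#' @param x Non-negative counts (or relative abundances) per taxon.
#' @param q Order of the Hill number (non-negative real; 0, 1, 2 typical).
#' @return The effective number of taxa, or `NA` when the community is empty.
#' @export
#' @examples
#' hill_number(c(10, 10, 10), q = 1) # 3 effective taxa
#' hill_number(c(8, 1, 1), q = 2)
hill_number <- function(x, q) {
  if (!is.numeric(x) || any(x < 0, na.rm = TRUE)) abort("`x` must be non-negative.")
  x <- x[!is.na(x) & x > 0]
  if (length(x) == 0 || sum(x) == 0) {
    warn("Empty community: Hill number undefined, returning NA.")
    return(NA_real_)
  }
  p <- x / sum(x)
  if (q == 0) {
    length(p)
  } else if (abs(q - 1) < 1e-12) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

#' Estimated sample coverage of a reference sample
#'
#' Coverage is the probability that the next individual sampled belongs to a
#' taxon already observed; it is the currency in which samples of unequal
#' effort are compared fairly. The estimator uses the singleton and doubleton
#' frequencies:
#' `C = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`.
#'
#' @inheritParams hill_number
#' @return Coverage in `[0, 1]`; `NA` for an empty sample.
#' @export
#' @examples
#' estimate_coverage(c(4, 3, 2, 1))
estimate_coverage <- function(x) {
  s <- abundance_stats(x)
  if (s$n == 0) {
    warn("Empty sample: coverage undefined, returning NA.")
    return(NA_real_)
  }
  if (s$f1 == 0) return(1)
  denom <- (s$n - 1) * s$f1 + 2 * s$f2
  a <- if (denom > 0) (s$n - 1) * s$f1 / denom else 1
  1 - (s$f1 / s$n) * a
}

# Extrapolation coefficient for coverage beyond the reference sample; the
# f2 = 0 case uses the standard (f1 - 1) substitute so extrapolation remains
# possible when no doubletons were observed.
cov_extrap_A <- function(n, f1, f2) {
  if (f1 == 0) return(NA_real_)
  if (f2 > 0) {
    (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
  } else if (f1 > 1) {
    (n - 1) * (f1 - 1) / ((n - 1) * (f1 - 1) + 2)
  } else {
    0
  }
}

# Coverage expected for a subsample of (real-valued) size m <= n - 1,
# hypergeometric expectation; for m >= n the f1/f2 extrapolation.
coverage_at_size <- function(x, m) {
  s <- abundance_stats(x)
  n <- s$n
  if (n == 0) return(NA_real_)
  x <- round(x[x > 0])
  vapply(m, function(mi) {
    if (mi < n) {
      terms <- (x / n) * exp(lchoose_gen(n - x, mi) - lchoose_gen(rep(n - 1, length(x)), mi))
      max(0, min(1, 1 - sum(terms)))
    } else {
      if (s$f1 == 0) return(1)
      a <- cov_extrap_A(n, s$f1, s$f2)
      1 - (s$f1 / n) * a^(mi - n + 1)
    }
  }, numeric(1))
}

#' Rarefied species richness
#'
#' Expected number of taxa in a random subsample of `m` individuals drawn
#' without replacement (the exact hypergeometric expectation), computed in
#' log space for numerical stability.
#'
#' @inheritParams hill_number
#' @param m Subsample size, `1 <= m <= sum(x)`.
#' @return Expected richness at size `m`.
#' @export
#' @examples
#' rarefy_richness(c(4, 3, 2, 1), m = 5)
rarefy_richness <- function(x, m) {
  s <- abundance_stats(x)
  if (any(m > s$n)) abort("`m` exceeds the sample size; use extrapolation instead.")
  if (any(m < 1)) abort("`m` must be at least 1.")
  x <- round(x[x > 0])
  n <- s$n
  vapply(m, function(mi) {
    sum(1 - exp(lchoose_gen(n - x, mi) - lchoose_gen(rep(n, length(x)), mi)))
  }, numeric(1))
}

# Chao1-style estimate of the number of unseen taxa.
unseen_taxa <- function(s) {
  if (s$f2 > 0) {
    ((s$n - 1) / s$n) * s$f1^2 / (2 * s$f2)
  } else {
    ((s$n - 1) / s$n) * s$f1 * (s$f1 - 1) / 2
  }
}

# Chao-Wang-Jost asymptotic Shannon entropy estimator.
entropy_asymptotic <- function(x) {
  x <- round(x[x > 0])
  n <- sum(x)
  if (n <= 1) return(0)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  part1 <- sum(vapply(x[x <= n - 1], function(xi) {
    (xi / n) * sum(1 / seq(xi, n - 1))
  }, numeric(1)))
  if (f1 == 0) return(part1)
  A <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2) else if (f1 > 1) 2 / ((n - 1) * (f1 - 1) + 2) else 1
  part2 <- 0
  if (A < 1) {
    r <- seq_len(n - 1)
    part2 <- (f1 / n) * (1 - A)^(1 - n) * (-log(A) - sum((1 / r) * (1 - A)^r))
  }
  part1 + part2
}

# Hill number at a (real-valued) sample size m, interpolated (m <= n) or
# extrapolated (m > n) with the standard coverage-based machinery.
hill_at_size <- function(x, m, q) {
  s <- abundance_stats(x)
  n <- s$n
  if (n == 0) return(NA_real_)
  x <- round(x[x > 0])
  if (q == 2) {
    # closed form, valid on both sides of n
    simp <- sum(x * (x - 1)) / (n * (n - 1))
    return(1 / (1 / m + (1 - 1 / m) * simp))
  }
  if (m <= n) {
    if (q == 0) {
      sum(1 - exp(lchoose_gen(n - x, m) - lchoose_gen(rep(n, length(x)), m)))
    } else {
      # expected plug-in Shannon entropy of the subsample: for each taxon,
      # E[-(X/m) log(X/m)] with X hypergeometric, summed over the effective
      # support only (mean +/- 10 SD), so cost is O(S * sqrt(m)) rather than
      # O(S * max count)
      mi <- max(1L, as.integer(round(m)))
      H <- 0
      for (i in seq_along(x)) {
        mu <- mi * x[i] / n
        sdv <- sqrt(max(mu * (1 - x[i] / n) * (n - mi) / max(n - 1, 1), 0))
        k_lo <- max(1, floor(mu - 10 * sdv - 5))
        k_hi <- min(mi, x[i], ceiling(mu + 10 * sdv + 5))
        if (k_hi < k_lo) next
        ks <- k_lo:k_hi
        pk <- stats::dhyper(ks, x[i], n - x[i], mi)
        H <- H - sum(pk * (ks / mi) * log(ks / mi))
      }
      exp(H)
    }
  } else {
    mstar <- m - n
    if (q == 0) {
      f0 <- unseen_taxa(s)
      if (f0 == 0 || s$f1 == 0) return(s$S_obs)
      s$S_obs + f0 * (1 - (1 - s$f1 / (n * f0 + s$f1))^mstar)
    } else {
      h_obs <- -sum((x / n) * log(x / n))
      h_inf <- entropy_asymptotic(x)
      exp((n / m) * h_obs + (mstar / m) * h_inf)
    }
  }
}

# Invert coverage -> sample size. Returns list(m, basis).
size_for_coverage <- function(x, target_C, q, extrap_cap = 2) {
  s <- abundance_stats(x)
  n <- s$n
  c_ref <- estimate_coverage(x)
  if (target_C <= c_ref + 1e-12) {
    if (abs(target_C - c_ref) < 1e-12) return(list(m = n, basis = "observed"))
    f <- function(m) coverage_at_size(x, m) - target_C
    if (f(1) >= 0) return(list(m = 1, basis = "rarefied"))
    m <- stats::uniroot(f, c(1, n), tol = 1e-8)$root
    list(m = m, basis = "rarefied")
  } else {
    if (s$f1 == 0) {
      # coverage already 1; nothing beyond the reference sample is attainable
      abort("Target coverage exceeds the attainable coverage; lower the target.")
    }
    a <- cov_extrap_A(n, s$f1, s$f2)
    m <- if (!is.na(a) && a <= 0) {
      # a single singleton and no doubletons: estimated coverage reaches 1
      # immediately beyond the reference sample
      n + 1
    } else if (is.na(a) || a >= 1 || target_C >= 1) {
      abort("Target coverage exceeds the attainable coverage; lower the target.")
    } else {
      mstar <- log(n * (1 - target_C) / s$f1) / log(a) - 1
      n + max(0, mstar)
    }
    if (q == 0) {
      # relative tolerance: the default target policy can land exactly on
      # the cap, and the log-space inversion round-trips with ~1e-12
      # relative error
      if (m > extrap_cap * n * (1 + 1e-6)) {
        abort(sprintf(
          "Target coverage %.4f requires extrapolation beyond %g times the sample size (richness cap); lower the target.",
          target_C, extrap_cap
        ))
      }
      m <- min(m, extrap_cap * n)
    }
    list(m = m, basis = "extrapolated")
  }
}

# Coverage-adjusted community estimate for bootstrapping: observed relative
# abundances shrunk to the estimated coverage, plus unseen taxa sharing the
# remaining probability (Chao-Jost unseen-species adjustment).
bootstrap_probs <- function(x) {
  x <- round(x[x > 0])
  n <- sum(x)
  c_ref <- estimate_coverage(x)
  p <- x / n
  w <- (1 - p)^n
  denom <- sum(p * w)
  lambda <- if (denom > 0) (1 - c_ref) / denom else 0
  p_adj <- p * (1 - lambda * w)
  f0 <- ceiling(unseen_taxa(abundance_stats(x)))
  p0 <- max(0, 1 - sum(p_adj))
  if (f0 > 0 && p0 > 0) c(p_adj, rep(p0 / f0, f0)) else p_adj / sum(p_adj)
}

#' Coverage-standardized diversity estimate
#'
#' Estimates the Hill number of order `q` at a stated target sample coverage,
#' interpolating (rarefying) when the target lies below the coverage of the
#' reference sample and extrapolating (via the singleton/doubleton asymptotics)
#' when it lies above. Uncertainty comes from a multinomial bootstrap of the
#' coverage-adjusted community.
#'
#' @inheritParams hill_number
#' @param target_C Target sample coverage in `(0, 1]`.
#' @param q Hill order (0, 1 or 2).
#' @param n_boot Bootstrap replicates for the percentile CI (0 to skip).
#' @param seed Integer seed for the bootstrap.
#' @param extrap_cap Extrapolation cap for `q = 0`, as a multiple of the
#'   reference sample size (default 2; richness extrapolation is unreliable
#'   beyond twice the sample size).
#' @return A one-row tibble: `q`, `coverage_target`, `m` (standardized sample
#'   size), `value`, `ci_low`, `ci_high`, `basis` (observed / rarefied /
#'   extrapolated).
#' @export
#' @examples
#' estimate_at_coverage(c(25, 10, 6, 3, 1, 1), target_C = 0.9, q = 1, n_boot = 50, seed = 1)
estimate_at_coverage <- function(x, target_C, q, n_boot = 200, seed = 1, extrap_cap = 2) {
  if (target_C <= 0 || target_C > 1) abort("`target_C` must be in (0, 1].")
  s <- abundance_stats(x)
  if (s$n == 0) abort("Empty sample: cannot standardize by coverage.")
  sz <- size_for_coverage(x, target_C, q, extrap_cap)
  value <- hill_at_size(x, sz$m, q)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    probs <- bootstrap_probs(x)
    boot <- local_seed(seed, {
      draws <- rmultinom(n_boot, size = s$n, prob = probs)
      apply(draws, 2, function(xb) {
        xb <- xb[xb > 0]
        if (length(xb) == 0) return(NA_real_)
        szb <- tryCatch(size_for_coverage(xb, target_C, q, extrap_cap),
                        error = function(e) NULL)
        if (is.null(szb)) return(NA_real_)
        hill_at_size(xb, szb$m, q)
      })
    })
    ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  }
  tibble::tibble(
    q = q, coverage_target = target_C, m = sz$m, value = value,
    ci_low = ci[1], ci_high = ci[2], basis = sz$basis
  )
}

#' Community evenness
#'
#' A `[0, 1]` summary of how equally abundance is spread among taxa,
#' separating relative-abundance structure from richness. The default formula
#' is the normalized Hill ratio `(D1 - 1) / (D0 - 1)`; `"log_ratio"` selects
#' `ln(D1) / ln(D0)` instead. Both equal 1 for a perfectly even community.
#'
#' @inheritParams hill_number
#' @param formula_id `"hill_ratio"` (default) or `"log_ratio"`.
#' @return Evenness in `[0, 1]`, or `NA` when fewer than two taxa are present.
#' @export
#' @examples
#' evenness(c(8, 1, 1))
evenness <- function(x, formula_id = c("hill_ratio", "log_ratio")) {
  formula_id <- match.arg(formula_id)
  x <- x[!is.na(x) & x > 0]
  if (length(x) < 2) {
    warn("Evenness undefined for fewer than 2 taxa; returning NA.")
    return(NA_real_)
  }
  d0 <- hill_number(x, 0)
  d1 <- hill_number(x, 1)
  switch(formula_id,
    hill_ratio = (d1 - 1) / (d0 - 1),
    log_ratio = log(d1) / log(d0)
  )
}

# Evenness from two coverage-standardized Hill numbers.
evenness_from_hill <- function(d0, d1, formula_id = "hill_ratio") {
  if (is.na(d0) || is.na(d1) || d0 <= 1) return(NA_real_)
  switch(formula_id,
    hill_ratio = (d1 - 1) / (d0 - 1),
    log_ratio = log(d1) / log(d0)
  )
}

#' Coverage-standardized diversity time series
#'
#' Computes one standardized estimate per metric per site-year at a common
#' coverage target. By default the target is the minimum, across years, of the
#' coverage attainable at twice each year's sample size (the standard
#' convention for comparing a series of unequal-effort samples); a fixed
#' target can be supplied instead.
#'
#' @param matrix A site-year matrix as returned by [pool_site_year_matrix()]:
#'   a tibble with a `year` column and one count column per taxon.
#' @param metrics Character subset of `c("q0", "q1", "q2", "evenness")`.
#' @param grouping `"all"`, `"mobile"` or `"sessile"`; the latter two require
#'   `mobility`.
#' @param mobility Optional named character vector (taxon -> "mobile" /
#'   "sessile") used when `grouping != "all"`.
#' @param coverage_target Optional fixed coverage target; `NULL` (default)
#'   uses the minimum attainable-at-2n coverage across years.
#' @param n_boot,seed Bootstrap settings passed to [estimate_at_coverage()].
#' @param evenness_formula Evenness definition, see [evenness()].
#' @return A long tibble: `year`, `group`, `metric`, `estimate`, `ci_low`,
#'   `ci_high`, `coverage`, `basis`. Years with no individuals in the chosen
#'   group appear with `NA` estimates.
#' @export
diversity_time_series <- function(matrix, metrics = c("q0", "q1", "q2", "evenness"),
                                  grouping = c("all", "mobile", "sessile"),
                                  mobility = NULL, coverage_target = NULL,
                                  n_boot = 200, seed = 1,
                                  evenness_formula = "hill_ratio") {
  grouping <- match.arg(grouping)
  metrics <- match.arg(metrics, c("q0", "q1", "q2", "evenness"), several.ok = TRUE)
  stopifnot(is.data.frame(matrix), "year" %in% names(matrix))
  taxa <- setdiff(names(matrix), "year")
  if (grouping != "all") {
    if (is.null(mobility)) abort("`mobility` required when grouping != 'all'.")
    taxa <- taxa[!is.na(mobility[taxa]) & mobility[taxa] == grouping]
  }
  counts <- as.matrix(matrix[, taxa, drop = FALSE])
  years <- matrix$year
  vecs <- lapply(seq_along(years), function(i) {
    xi <- counts[i, ]
    round(xi[xi > 0])
  })
  nonempty <- vapply(vecs, function(v) sum(v) > 0, logical(1))
  if (is.null(coverage_target)) {
    if (!any(nonempty)) abort("No year has any individuals in the chosen group.")
    cov2n <- vapply(vecs[nonempty], function(v) coverage_at_size(v, 2 * sum(v)), numeric(1))
    coverage_target <- min(cov2n)
  }
  needs <- unique(unlist(lapply(metrics, function(m) switch(m,
    q0 = 0, q1 = 1, q2 = 2, evenness = c(0, 1)
  ))))
  rows <- purrr::map_dfr(seq_along(years), function(i) {
    if (!nonempty[i]) {
      return(tibble::tibble(
        year = years[i], group = grouping, metric = metrics,
        estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        coverage = coverage_target, basis = NA_character_
      ))
    }
    ests <- lapply(needs, function(q) {
      estimate_at_coverage(vecs[[i]], coverage_target, q,
                           n_boot = n_boot, seed = seed + 1000L * q + i)
    })
    names(ests) <- paste0("q", needs)
    purrr::map_dfr(metrics, function(m) {
      if (m == "evenness") {
        est <- evenness_from_hill(ests$q0$value, ests$q1$value, evenness_formula)
        lo <- evenness_from_hill(ests$q0$value, ests$q1$ci_low, evenness_formula)
        hi <- evenness_from_hill(ests$q0$value, ests$q1$ci_high, evenness_formula)
        tibble::tibble(
          year = years[i], group = grouping, metric = m, estimate = est,
          ci_low = lo, ci_high = hi, coverage = coverage_target,
          basis = ests$q1$basis
        )
      } else {
        e <- ests[[m]]
        tibble::tibble(
          year = years[i], group = grouping, metric = m, estimate = e$value,
          ci_low = e$ci_low, ci_high = e$ci_high, coverage = coverage_target,
          basis = e$basis
        )
      }
    })
  })
  class(rows) <- c("shore_diversity_series", class(rows))
  rows
}
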