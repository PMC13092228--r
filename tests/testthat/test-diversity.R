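test_that("Hill numbers match direct formula evaluations", {
  # perfectly even community: every order gives S
  for (q in c(0, 1, 2, 0.5, 1.7)) {
    expect_equal(hill_number(c(10, 10, 10), q), 3, tolerance = 1e-12)
  }
  expect_equal(hill_number(c(8, 1, 1), 1), exp(0.639032), tolerance = 1e-5)
  expect_equal(hill_number(c(8, 1, 1), 2), 1 / 0.66, tolerance = 1e-10)
  expect_warning(expect_true(is.na(hill_number(numeric(0), 1))), "Empty")
})

test_that("the generic-q formula is continuous at q = 1", {
  set.seed(2)
  for (i in 1:20) {
    x <- rpois(15, 5); x <- x[x > 0]
    if (length(x) < 2) next
    expect_equal(hill_number(x, 1), hill_number(x, 1 + 1e-9), tolerance = 1e-6)
    expect_equal(hill_number(x, 1), hill_number(x, 1 - 1e-9), tolerance = 1e-6)
  }
})

test_that("diversity is non-increasing in q", {
  set.seed(3)
  for (i in 1:25) {
    x <- rnbinom(20, mu = 4, size = 0.8); x <- x[x > 0]
    if (length(x) < 2) next
    d <- vapply(c(0, 0.5, 1, 1.5, 2), function(q) hill_number(x, q), numeric(1))
    expect_true(all(diff(d) <= 1e-10))
  }
})

test_that("sample coverage matches its closed form", {
  expect_equal(estimate_coverage(c(2, 2)), 1)
  expect_equal(estimate_coverage(c(4, 3, 2, 1)), 1 - 0.1 * (9 / 11), tolerance = 1e-12)
  expect_equal(estimate_coverage(1), 0)
})

test_that("rarefied richness matches exact and enumerated oracles", {
  x <- c(4, 3, 2, 1)
  expect_equal(rarefy_richness(x, sum(x)), 4)      # m = n recovers S_obs
  expect_equal(rarefy_richness(x, 1), 1)           # one individual, one taxon
  expect_equal(rarefy_richness(x, 5), 3.170635, tolerance = 1e-5)

  # exhaustive enumeration over all C(n, m) subsamples for n <= 12
  for (x in list(c(5, 4, 2, 1), c(6, 3, 1), c(2, 2, 2, 2, 2))) {
    n <- sum(x)
    lab <- rep(seq_along(x), x)
    for (m in c(2, 5, n - 1)) {
      enum <- mean(apply(utils::combn(n, m), 2,
                         function(id) length(unique(lab[id]))))
      expect_equal(rarefy_richness(x, m), enum, tolerance = 1e-9)
    }
  }
})

test_that("rarefied richness agrees with Monte-Carlo subsampling at larger n", {
  set.seed(9)
  x <- rnbinom(40, mu = 8, size = 1); x <- x[x > 0]
  n <- sum(x)
  lab <- rep(seq_along(x), x)
  m <- round(n / 3)
  draws <- replicate(50000, length(unique(lab[sample.int(n, m)])))
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(rarefy_richness(x, m) - mean(draws)), 3 * mc_se)
  # independent cross-check against vegan's implementation
  expect_equal(rarefy_richness(x, m), as.numeric(vegan::rarefy(x, m)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("coverage is non-decreasing in subsample size", {
  set.seed(4)
  for (i in 1:5) {
    x <- rnbinom(25, mu = 5, size = 1); x <- x[x > 0]
    cs <- shoretrends:::coverage_at_size(x, seq(1, 2.5 * sum(x), length.out = 80))
    expect_true(all(diff(cs) >= -1e-9))
  }
})

test_that("coverage standardization is anchored at the reference sample", {
  x <- c(4, 3, 2, 1)
  e <- estimate_at_coverage(x, estimate_coverage(x), q = 0, n_boot = 0)
  expect_equal(e$value, 4)
  expect_equal(e$basis, "observed")

  # interpolated richness at the coverage of m = 5 matches exact rarefaction
  e5 <- estimate_at_coverage(x, shoretrends:::coverage_at_size(x, 5), q = 0, n_boot = 0)
  expect_equal(e5$value, rarefy_richness(x, 5), tolerance = 1e-6)
  expect_equal(e5$basis, "rarefied")
})

test_that("bootstrap intervals are seed-reproducible and respect the cap", {
  x <- c(25, 10, 6, 3, 1, 1)
  a <- estimate_at_coverage(x, 0.95, q = 1, n_boot = 100, seed = 42)
  b <- estimate_at_coverage(x, 0.95, q = 1, n_boot = 100, seed = 42)
  expect_identical(a, b)
  c2 <- estimate_at_coverage(x, 0.95, q = 1, n_boot = 100, seed = 43)
  expect_false(identical(a$ci_low, c2$ci_low))
  # richness extrapolation is capped at twice the sample size
  expect_error(estimate_at_coverage(x, 0.9999, q = 0, n_boot = 0), "cap|lower the target")
})

test_that("evenness formulas behave on the unit interval", {
  expect_equal(evenness(c(7, 7, 7, 7)), 1)
  expect_equal(evenness(c(8, 1, 1)), (hill_number(c(8, 1, 1), 1) - 1) / 2,
               tolerance = 1e-12)
  expect_lt(evenness(c(98, 1, 1)), evenness(c(8, 1, 1)))
  expect_gt(evenness(c(98, 1, 1)), 0)
  lr <- evenness(c(8, 1, 1), formula_id = "log_ratio")
  expect_true(lr > 0 && lr < 1)
  expect_warning(expect_true(is.na(evenness(c(5)))), "fewer than 2")
})

test_that("diversity time series standardizes at a common coverage", {
  # identical columns in two years -> identical estimates
  mat <- tibble::tibble(year = c("2016", "2017"),
                        A = c(12, 12), B = c(6, 6), C = c(2, 2), D = c(1, 1))
  ts <- diversity_time_series(mat, metrics = c("q0", "q1"), n_boot = 0)
  for (m in c("q0", "q1")) {
    est <- ts$estimate[ts$metric == m]
    expect_equal(est[1], est[2], tolerance = 1e-10)
  }

  # increasing dominance at constant richness: q1, q2, evenness decline
  # while q0 stays flat (all counts >= 2 so each year is fully covered)
  mat2 <- tibble::tibble(year = as.character(2016:2018),
                         A = c(10, 24, 60), B = c(10, 6, 4),
                         C = c(10, 5, 3), D = c(10, 5, 3))
  ts2 <- diversity_time_series(mat2, n_boot = 0)
  for (m in c("q1", "q2", "evenness")) {
    est <- ts2$estimate[ts2$metric == m]
    expect_true(all(diff(est) < 0), info = m)
  }
  expect_equal(unique(ts2$estimate[ts2$metric == "q0"]), 4)
})

test_that("groups with no individuals in a year come back missing, not zero", {
  mat <- tibble::tibble(year = c("2016", "2017"), A = c(5, 0), B = c(3, 0),
                        C = c(0, 8), D = c(2, 6))
  mob <- c(A = "mobile", B = "mobile", C = "sessile", D = "sessile")
  ts <- diversity_time_series(mat, metrics = "q1", grouping = "mobile",
                              mobility = mob, n_boot = 0)
  expect_true(is.na(ts$estimate[ts$year == "2017"]))
  expect_false(is.na(ts$estimate[ts$year == "2016"]))
  expect_error(diversity_time_series(mat, grouping = "mobile", n_boot = 0),
               "mobility")
})
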