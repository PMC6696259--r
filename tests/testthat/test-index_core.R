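test_that("standardization is the plain Z transform with sample SD", {
  expect_equal(standardize(2, 2, 1), 0)
  expect_equal(standardize(3, 2, 1), 1)
  # {1,2,3}: sample mean 2, sample sd 1
  expect_equal(standardize(3, mean(1:3), stats::sd(1:3)), 1)
  expect_error(standardize(1, 0, 0), "sd must be > 0")
  expect_true(is.na(standardize(NA, 0.05, 0.01)))
})

test_that("climatology pools a month across years and counts pairs", {
  s10 <- make_series(seq(0.04, 0.06, length.out = 10), start = "2010-05-01")
  clim <- fit_climatology(s10, 5, fit_years = 2010)
  expect_equal(clim$n_obs, 10)
  expect_equal(clim$mean_aphy, mean(s10$aphy))
  expect_equal(clim$sd_aphy, stats::sd(s10$aphy))

  # pooled across years, not per-year: two years with different levels
  two <- pixel_series(c(as.Date("2010-05-01") + 0:4, as.Date("2011-05-01") + 0:4),
                      c(rep(0.04, 5), rep(0.06, 5)) + (1:10) * 1e-4,
                      rep(0.04, 10) + (1:10) * 1e-4)
  clim2 <- fit_climatology(two, 5)
  expect_equal(clim2$n_obs, 10)
  expect_equal(clim2$mean_aphy, mean(two$aphy))

  expect_error(fit_climatology(make_series(rep(0.05, 10)), 5), "sd <= 0")
  expect_error(fit_climatology(make_series(0.05), 5), ">= 2 paired")
  # other-month data are invisible to the fit
  expect_error(fit_climatology(s10, 6), ">= 2 paired")
})

test_that("fitted climatology recovers the generator's configured moments", {
  cfg <- synth_config(years = 2003:2016, months = 5, base_mean_aphy = 0.05,
                      cv = 0.4, missing_prob = 0, seed = 14)
  sim <- simulate_series(cfg)
  clim <- fit_climatology(sim$series, 5)
  se <- clim$sd_aphy / sqrt(clim$n_obs)
  expect_lt(abs(clim$mean_aphy - 0.05), 3 * se)
})

test_that("leading eigenpair has the analytic 2x2 closed form", {
  z <- c(-1.2, 0.3, 0.8, -0.4, 1.1, -0.6)
  # perfect correlation
  s <- fit_soef(z, 2 * z)
  expect_equal(unname(s$b), c(1, 1) / sqrt(2), tolerance = 1e-9)
  expect_equal(s$eigenvalues, c(2, 0), tolerance = 1e-9)
  # perfect anticorrelation: orientation keeps the aphy loading positive
  s2 <- fit_soef(z, -z)
  expect_equal(unname(s2$b), c(1, -1) / sqrt(2), tolerance = 1e-9)
  expect_equal(s2$eigenvalues[1], 2, tolerance = 1e-9)
  expect_error(fit_soef(1, 1), ">= 2")
  expect_error(fit_soef(c(0, 0, 0), c(1, 2, 3)), "non-constant")
})

test_that("for any sample correlation r: lambda1 = 1 + |r|, b = (1, sign(r))/sqrt(2)", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n) * sample(c(-1, 1), 1) + z1 * stats::runif(1, -1, 1)
    s <- fit_soef(z1, z2)
    r <- stats::cor(z1, z2)
    expect_equal(s$eigenvalues[1], 1 + abs(r), tolerance = 1e-9)
    expect_equal(sum(s$b^2), 1, tolerance = 1e-9)
    expect_equal(sum(s$eigenvalues), 2, tolerance = 1e-9)
    expect_equal(unname(s$b), c(1, sign(r)) / sqrt(2), tolerance = 1e-9)
    expect_true(s$b[["b11"]] >= 0)
  }
})

test_that("eigen-decomposition matches the characteristic-polynomial oracle", {
  set.seed(77)
  for (i in 1:200) {
    z1 <- stats::rnorm(20)
    z2 <- stats::runif(1, -1, 1) * z1 + stats::rnorm(20)
    s <- fit_soef(z1, z2)
    o <- eig2_oracle(matrix(c(1, s$rho, s$rho, 1), 2))
    expect_equal(unname(s$eigenvalues), o$values, tolerance = 1e-9)
    expect_equal(unname(s$b), o$vector, tolerance = 1e-9)
  }
})

test_that("uncorrelated pair is flagged degenerate with the (1, 0) fallback", {
  z1 <- c(1, 1, -1, -1)
  z2 <- c(1, -1, 1, -1)  # exactly zero sample correlation
  s <- fit_soef(z1, z2)
  expect_true(s$degenerate)
  expect_equal(unname(s$b), c(1, 0))
})

test_that("index is the eigenvector-weighted sum of the standardized pair", {
  b <- structure(list(b = c(b11 = 0.70711, b12 = 0.70711),
                      eigenvalues = c(1.6, 0.4), rho = 0.6, n = 10,
                      degenerate = FALSE), class = "soef_model")
  expect_equal(compute_index(0, 0, b), 0)
  expect_equal(compute_index(1, 1, b), 1.41422)
  expect_equal(compute_index(2, -1, b), 0.70711)
  expect_true(is.na(compute_index(NA, 1, b)))
})

test_that("the active threshold is the two-sided 90% normal quantile", {
  expect_equal(icdf_threshold(0.90), 1.6448536, tolerance = 1e-6)
  expect_equal(round(icdf_threshold(0.90), 1), 1.6)
  expect_equal(icdf_threshold(0.95), 1.959964, tolerance = 1e-6)
  expect_lt(icdf_threshold(1e-9), 1e-8)  # vanishing confidence, vanishing threshold
  expect_error(icdf_threshold(0), "confidence")
  expect_error(icdf_threshold(1), "confidence")
  expect_equal(class_thresholds()$active, 1.6)
  expect_error(class_thresholds(pre_alert = 2), "pre_alert < active")
})

test_that("classification bands are left-closed and exhaustive", {
  th <- class_thresholds()
  expect_equal(as.character(classify(c(0.5, 1.3, 2.0), th)),
               c("NON_BLOOM", "PRE_ALERT", "ACTIVE_BLOOM"))
  # boundary convention: thresholds belong to the upper band
  expect_equal(as.character(classify(1.0, th)), "PRE_ALERT")
  expect_equal(as.character(classify(1.6, th)), "ACTIVE_BLOOM")
  # strongly negative anomalies are non-bloom but flagged
  expect_equal(as.character(classify(-1.24, th)), "NON_BLOOM")
  expect_true(negative_anomaly(-1.24, th))
  expect_false(negative_anomaly(0.5, th))
  expect_true(is.na(classify(NA_real_, th)))
  # monotone non-decreasing in the index
  x <- sort(stats::rnorm(200, sd = 2))
  lab <- classify(x, th)
  expect_true(all(diff(as.integer(lab)) >= 0))
})

test_that("gap-free baselines are exactly zero and index variance equals lambda1", {
  sim <- simulate_series(synth_config(years = 2003:2008, months = 5,
                                      missing_prob = 0, rho = 0.6, seed = 18))
  bl <- fit_baseline(sim$series, 5)
  expect_lt(abs(bl$baseline_index), 1e-12)
  # applied Z series have sample mean 0, sd 1 on the fitting set
  clim <- bl$climatology
  z1 <- standardize(sim$series$aphy, clim$mean_aphy, clim$sd_aphy)
  expect_lt(abs(mean(z1)), 1e-9)
  expect_equal(stats::sd(z1), 1, tolerance = 1e-9)
  idx <- compute_index_series(sim$series, bl)
  expect_equal(stats::var(idx$index), bl$soef$eigenvalues[1], tolerance = 1e-9)
})

test_that("disjoint fitting windows give independent frozen models", {
  sim <- simulate_series(synth_config(years = 2003:2012, months = 5,
                                      missing_prob = 0, seed = 19))
  b1 <- fit_baseline(sim$series, 5, fit_years = 2003:2007)
  b2 <- fit_baseline(sim$series, 5, fit_years = 2008:2012)
  expect_equal(b1$fit_period, c(2003, 2007))
  expect_false(isTRUE(all.equal(b1$climatology$mean_aphy, b2$climatology$mean_aphy)))
  # scoring new years against a frozen model refits nothing
  idx_new <- compute_index_series(sim$series, b1, years = 2008:2012)
  expect_equal(nrow(idx_new), sum(year_of(sim$series$date) %in% 2008:2012))
  refit <- fit_baseline(sim$series, 5, fit_years = 2003:2007)
  expect_equal(refit$soef$b, b1$soef$b)
})

test_that("pair-incomplete days get missing index but full days are scored", {
  sim <- simulate_series(synth_config(years = 2003:2006, months = 5,
                                      missing_prob = 0.3, seed = 23))
  bl <- fit_baseline(sim$series, 5)
  idx <- compute_index_series(sim$series, bl)
  expect_equal(sum(!is.na(idx$index)), sum(pair_complete(sim$series)))
  expect_true(all(is.na(idx$label) == is.na(idx$index)))
})

test_that("baseline models survive a JSON round trip at full precision", {
  skip_if_not_installed("jsonlite")
  sim <- simulate_series(synth_config(years = 2003:2006, months = 6,
                                      missing_prob = 0.2, seed = 27))
  bl <- fit_baseline(sim$series, 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_baseline_json(bl, path)
  bl2 <- read_baseline_json(path)
  expect_equal(bl2$climatology$mean_aphy, bl$climatology$mean_aphy)
  expect_equal(bl2$soef$b, bl$soef$b)
  expect_equal(bl2$baseline_index, bl$baseline_index)
  idx1 <- compute_index_series(sim$series, bl)
  idx2 <- compute_index_series(sim$series, bl2)
  expect_equal(idx1$index, idx2$index)
})
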