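test_that("frequency table reproduces exact counts and extrema", {
  idx <- make_index_series(c(0.5, 1.2, 2.0, 0.1))
  ft <- frequency_table(idx)
  expect_equal(ft$pct_non_bloom, 50)
  expect_equal(ft$pct_pre_alert, 25)
  expect_equal(ft$pct_active, 25)
  expect_equal(ft$min_index, 0.1)
  expect_equal(ft$max_index, 2.0)
  expect_equal(ft$n, 4)

  all_low <- frequency_table(make_index_series(c(-0.5, 0.2, 0.9)))
  expect_equal(all_low$pct_non_bloom, 100)
  expect_equal(all_low$pct_active, 0)

  expect_error(frequency_table(make_index_series(NA_real_)), "no non-missing")
})

test_that("an engineered 81/13/6 composition is reported as 81/13/6", {
  # synthetic stand-in shaped like a monitoring point's May record
  set.seed(61)
  vals <- c(stats::runif(81, -0.9, 0.9), stats::runif(13, 1.05, 1.55),
            stats::runif(6, 1.65, 5.0))
  ft <- frequency_table(make_index_series(sample(vals), dates = may_dates(100)))
  expect_equal(ft$pct_non_bloom, 81)
  expect_equal(ft$pct_pre_alert, 13)
  expect_equal(ft$pct_active, 6)
})

test_that("frequency percentages always sum to 100 and counts to n", {
  set.seed(62)
  for (i in 1:10) {
    n <- sample(5:200, 1)
    idx <- make_index_series(stats::rnorm(n, sd = 1.5), dates = may_dates(n))
    ft <- frequency_table(idx)
    expect_equal(ft$pct_non_bloom + ft$pct_pre_alert + ft$pct_active, 100)
    expect_equal(ft$n, n)
  }
})

test_that("presentation rounding goes half away from zero", {
  expect_equal(round_half_up(12.5), 13)
  expect_equal(round_half_up(12.4), 12)
  expect_equal(round_half_up(-12.5), -13)
})

test_that("annual exceedance counts per observed year, NA when unobserved", {
  # 2005: 8 observations, 1 exceedance -> 12.5%
  idx <- make_index_series(c(rep(0.2, 7), 1.7), start = "2005-05-01")
  idx2 <- make_index_series(rep(0.3, 5), start = "2007-05-01")
  both <- rbind(idx, idx2)
  ae <- annual_exceedance(both)
  expect_equal(ae$freq_pct[ae$year == 2005], 12.5)
  expect_equal(round_half_up(ae$freq_pct[ae$year == 2005]), 13)
  expect_true(is.na(ae$freq_pct[ae$year == 2006]))  # no data is not 0
  expect_equal(ae$freq_pct[ae$year == 2007], 0)
})

test_that("exceedances land only in the years carrying bloom days", {
  # truth-driven fixture: a decade of May records, anomalous days only in
  # the first era (mirroring a trend inversion)
  rows <- lapply(2003:2012, function(y) {
    v <- rep(0.3, 20)
    if (y <= 2006) v[5:6] <- 2.2
    make_index_series(v, start = sprintf("%d-05-01", y))
  })
  idx <- do.call(rbind, rows)
  ae <- annual_exceedance(idx)
  expect_true(all(ae$year[ae$freq_pct > 0] <= 2006))
  expect_equal(ae$freq_pct[ae$year == 2004], 10)
  expect_true(all(ae$freq_pct[ae$year >= 2007] == 0))
})

test_that("run lengths partition observed days; gaps break strict runs", {
  lab3 <- make_index_series(c(2.0, 2.1, 1.9))  # 3 consecutive active days
  r <- run_lengths(lab3)
  expect_equal(nrow(r), 1)
  expect_equal(r$state, "ACTIVE_BLOOM")
  expect_equal(r$length, 3)

  gap <- make_index_series(c(2.0, NA, 2.1))
  rs <- run_lengths(gap, mode = "strict")
  expect_equal(rs$length, c(1, 1))
  rb <- run_lengths(gap, mode = "bridge")
  expect_equal(rb$length, 2)       # observed days in the bridged run
  expect_equal(rb$span_days, 3)

  set.seed(63)
  vals <- stats::rnorm(60)
  vals[sample(60, 15)] <- NA
  mixed <- make_index_series(vals)
  rr <- run_lengths(mixed, mode = "strict")
  expect_equal(sum(rr$length), sum(!is.na(vals)))
})

test_that("a mostly-singleton bloom record yields a 1-dominated run histogram", {
  # sporadic exceedance pattern: isolated active days with one 2-day and one
  # 3-day episode, the rest non-bloom
  vals <- rep(0.2, 40)
  vals[c(5, 12, 30)] <- 2.0          # singletons
  vals[18:19] <- 2.2                 # one 2-day run
  vals[25:27] <- 2.5                 # one 3-day run
  r <- run_lengths(make_index_series(vals))
  act <- r[r$state == "ACTIVE_BLOOM", ]
  expect_equal(sort(act$length), c(1, 1, 1, 2, 3))
  expect_equal(sum(act$length == 1), 3)
})

test_that("trend split separates eras and flags an injected step change", {
  f <- tibble::tibble(year = 2003:2016,
                      freq_pct = c(8, 38, 25, 29, 12, 11, 20, rep(0, 7)))
  ts <- trend_split(f, 2010)
  expect_gt(ts$difference, 0)
  expect_equal(ts$mean_after, 0)
  expect_lt(ts$p_value, 0.05)

  same <- tibble::tibble(year = 2003:2010, freq_pct = rep(10, 8))
  expect_equal(trend_split(same, 2007)$difference, 0)
  expect_error(trend_split(same, 2003), "each side")
})

test_that("phytoplankton contribution fraction is the aphy share", {
  expect_equal(contribution_fraction(0.05, 0.05), 0.5)
  expect_equal(contribution_fraction(0.063, 0.037), 0.63)
  expect_equal(contribution_fraction(0.05, 0), 1)
  expect_true(is.na(contribution_fraction(0, 0)))
  expect_true(is.na(contribution_fraction(NA, 0.04)))
})

test_that("contribution summaries are averaged within each bloom state", {
  s <- make_series(c(0.05, 0.06, 0.09), c(0.05, 0.04, 0.01))
  idx <- make_index_series(c(0.2, 1.2, 2.0), start = "2010-05-01")
  cc <- contribution_by_class(s, idx)
  expect_equal(cc$mean_contribution_pct[cc$label == "NON_BLOOM"], 50)
  expect_equal(cc$mean_contribution_pct[cc$label == "PRE_ALERT"], 60)
  expect_equal(cc$mean_contribution_pct[cc$label == "ACTIVE_BLOOM"], 90)
})

test_that("rank correlation matches hand cases and rejects tiny samples", {
  expect_equal(spearman_validation(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman_validation(1:6, -(1:6))$rho, -1)
  # swapped-neighbour pairs, n = 6: sum d^2 = 6 -> rho = 1 - 36/210
  r <- spearman_validation(1:6, c(2, 1, 4, 3, 6, 5))
  expect_equal(r$rho, 1 - 36 / 210)
  expect_equal(r$rho, spearman_oracle(1:6, c(2, 1, 4, 3, 6, 5)))
  expect_equal(r$n, 6)
  expect_error(spearman_validation(1:3, 3:1), ">= 4")
})

test_that("rank correlation equals the rank oracle on all 720 permutations", {
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), , drop = FALSE]
  expect_equal(nrow(perms), 720)
  x <- 1:6
  for (i in seq_len(nrow(perms))) {
    y <- perms[i, ]
    expect_equal(spearman_validation(x, y)$rho, spearman_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("field samples match to the nearest valid satellite day or composite", {
  s <- make_series(c(0.05, NA, 0.07, NA, 0.09), c(0.04, NA, 0.05, NA, 0.06),
                   start = "2017-05-30")
  field <- tibble::tibble(station = c("st1", "st2"),
                          date = as.Date(c("2017-06-01", "2017-06-02")),
                          aphy_field = c(0.06, 0.08), adcdom_field = c(0.05, 0.05))
  m <- match_field_satellite(field, s, window_days = 8)
  # 2017-06-01: nearest valid is the same day; 05-31 is pair-incomplete
  expect_equal(m$aphy_sat[1], 0.07)
  expect_equal(m$matchup_lag_days[1], 0L)
  # 2017-06-02: 06-01 and 06-03 tie on distance; earlier day wins
  expect_equal(m$aphy_sat[2], 0.07)
  expect_equal(m$matchup_lag_days[2], -1L)
  comp <- match_field_satellite(field, s, window_days = 8, mode = "composite")
  expect_equal(comp$aphy_sat[1], mean(c(0.05, 0.07, 0.09)))
  m0 <- match_field_satellite(field, s, window_days = 0)
  expect_equal(nrow(m0), 1)  # the sample with no same-day overpass is dropped
  far <- tibble::tibble(station = "st3", date = as.Date("2019-01-01"),
                        aphy_field = 0.05, adcdom_field = 0.04)
  expect_error(match_field_satellite(far, s), "no field sample")
})
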