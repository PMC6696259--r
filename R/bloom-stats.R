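#' Interval frequencies and extrema of an index series
#'
#' Summarizes how often the index fell below the pre-alert threshold, in
#' the pre-alert band, and at or above the active-bloom threshold, as
#' percentages of the non-missing observations, together with the observed
#' minimum and maximum. One row per (point, month) combination present in
#' the series. Percentages are kept at full precision; use
#' [round_half_up()] when printing integer tables.
#'
#' @param index_series Tibble with `date`, `point_id`, `index` (from
#'   [compute_index_series()]).
#' @param thresholds A [class_thresholds()].
#' @return Tibble: `point_id`, `month`, `n`, `pct_non_bloom`,
#'   `pct_pre_alert`, `pct_active`, `min_index`, `max_index`.
#' @export
frequency_table <- function(index_series, thresholds = class_thresholds()) {
  obs <- index_series[!is.na(index_series$index), ]
  if (nrow(obs) == 0) stop("frequency_table: no non-missing index values", call. = FALSE)
  obs$month <- month_of(obs$date)
  key <- interaction(obs$point_id, obs$month, drop = TRUE)
  rows <- lapply(split(obs, key), function(g) {
    lab <- classify(g$index, thresholds)
    n <- nrow(g)
    tibble::tibble(
      point_id = g$point_id[1], month = g$month[1], n = n,
      pct_non_bloom = 100 * sum(lab == "NON_BLOOM") / n,
      pct_pre_alert = 100 * sum(lab == "PRE_ALERT") / n,
      pct_active    = 100 * sum(lab == "ACTIVE_BLOOM") / n,
      min_index = min(g$index), max_index = max(g$index)
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$point_id, out$month), ]
}

#' Round half away from zero
#'
#' Printed monitoring tables round 12.5 to 13, not to 12 as banker's
#' rounding would; computations stay at full precision and this rule is
#' applied only at presentation.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Yearly exceedance frequency of the active-bloom threshold
#'
#' For each (point, month, year): the percentage of observed days whose
#' index reached the threshold. Years inside `years` with no observations
#' in that month are reported with `NA` frequency — no data is not the
#' same as no blooms.
#'
#' @inheritParams frequency_table
#' @param threshold Exceedance threshold in SD units (default 1.6).
#' @param years Years to report; `NULL` = span of the series.
#' @return Tibble: `point_id`, `month`, `year`, `n_obs`, `n_exceed`,
#'   `freq_pct` (`NA` when `n_obs` is 0).
#' @export
annual_exceedance <- function(index_series, threshold = 1.6, years = NULL) {
  if (nrow(index_series) == 0) stop("annual_exceedance: empty series", call. = FALSE)
  obs <- index_series[!is.na(index_series$index), ]
  yr <- year_of(index_series$date)
  if (is.null(years)) years <- seq(min(yr), max(yr))
  months <- sort(unique(month_of(index_series$date)))
  pids <- unique(index_series$point_id)
  grid <- expand.grid(point_id = pids, month = months, year = years,
                      stringsAsFactors = FALSE)
  oy <- year_of(obs$date); om <- month_of(obs$date)
  n_obs <- mapply(function(p, m, y) sum(obs$point_id == p & om == m & oy == y),
                  grid$point_id, grid$month, grid$year)
  n_exc <- mapply(function(p, m, y) {
    sum(obs$point_id == p & om == m & oy == y & obs$index >= threshold)
  }, grid$point_id, grid$month, grid$year)
  tibble::tibble(
    point_id = grid$point_id, month = grid$month, year = grid$year,
    n_obs = as.integer(n_obs), n_exceed = as.integer(n_exc),
    freq_pct = ifelse(n_obs > 0, 100 * n_exc / n_obs, NA_real_)
  )
}

#' Run lengths of identical bloom states
#'
#' Measures the persistence of classified conditions as maximal runs of
#' the same label. In `strict` mode a run only extends across consecutive
#' calendar days with observations — a cloud-gap day breaks it, so run
#' lengths partition the observed days exactly. In `bridge` mode gaps
#' between equal-label observations are ignored (the gap-held reading);
#' `length` still counts observed days, with the calendar span in
#' `span_days`.
#'
#' @param labeled Tibble with `date` and `label` (`NA` label = missing day).
#' @param mode `"strict"` or `"bridge"`.
#' @return Tibble: `state`, `start_date`, `end_date`, `length` (observed
#'   days), `span_days` (calendar days from start to end inclusive).
#' @export
run_lengths <- function(labeled, mode = c("strict", "bridge")) {
  mode <- match.arg(mode)
  obs <- labeled[!is.na(labeled$label), ]
  obs <- obs[order(obs$date), ]
  empty <- tibble::tibble(state = character(), start_date = as.Date(character()),
                          end_date = as.Date(character()), length = integer(),
                          span_days = integer())
  if (nrow(obs) == 0) return(empty)
  lab <- as.character(obs$label)
  gap <- c(FALSE, diff(obs$date) != 1)     # TRUE where a calendar day is skipped
  new_run <- c(TRUE, lab[-1] != lab[-length(lab)])
  if (mode == "strict") new_run <- new_run | gap
  run_id <- cumsum(new_run)
  rows <- lapply(split(seq_along(run_id), run_id), function(i) {
    tibble::tibble(state = lab[i[1]],
                   start_date = obs$date[i[1]], end_date = obs$date[i[length(i)]],
                   length = length(i),
                   span_days = as.integer(obs$date[i[length(i)]] - obs$date[i[1]]) + 1L)
  })
  do.call(rbind, rows)
}

#' Before/after comparison of yearly exceedance frequencies
#'
#' Splits per-year exceedance frequencies at a given year and compares the
#' two eras: mean frequency before versus from the split year on, their
#' difference, and a two-sample rank test (Wilcoxon/Mann-Whitney) on the
#' per-year values — the appropriate test for small samples of bounded
#' percentages.
#'
#' @param annual_freqs Tibble from [annual_exceedance()] (or any tibble
#'   with `year` and `freq_pct`); `NA` frequencies are dropped.
#' @param split_year First year of the "after" era.
#' @return List: `mean_before`, `mean_after`, `difference`
#'   (before - after), `n_before`, `n_after`, `p_value`, `test`.
#' @export
trend_split <- function(annual_freqs, split_year) {
  f <- annual_freqs[!is.na(annual_freqs$freq_pct), ]
  before <- f$freq_pct[f$year < split_year]
  after  <- f$freq_pct[f$year >= split_year]
  if (length(before) == 0 || length(after) == 0) {
    stop("trend_split: need at least one observed year on each side", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(before, after, exact = FALSE))
  list(mean_before = mean(before), mean_after = mean(after),
       difference = mean(before) - mean(after),
       n_before = length(before), n_after = length(after),
       p_value = wt$p.value, test = "Wilcoxon rank-sum")
}

#' Phytoplankton share of total absorption
#'
#' Fraction of the combined absorption signal due to phytoplankton:
#' `aphy / (aphy + adcdom)`. Near 0.5 the two constituents contribute
#' equally; higher values indicate phytoplankton-dominated water, lower
#' values detritus/CDOM-dominated (decaying-bloom) water.
#'
#' @param aphy,adcdom Absorption coefficients (m^-1), vectors ok.
#' @return Fraction in \[0, 1\]; `NA` where the total is 0 or missing.
#' @export
contribution_fraction <- function(aphy, adcdom) {
  tot <- aphy + adcdom
  ifelse(!is.na(tot) & tot > 0, aphy / tot, NA_real_)
}

#' Mean phytoplankton contribution per bloom state
#'
#' Joins a raw series with its classified index days and reports the mean
#' phytoplankton contribution (%) within each state.
#'
#' @param series A [pixel_series()].
#' @param index_series Matching tibble from [compute_index_series()].
#' @return Tibble: `label`, `n`, `mean_contribution_pct`.
#' @export
contribution_by_class <- function(series, index_series) {
  m <- match(index_series$date, series$date)
  frac <- contribution_fraction(series$aphy[m], series$adcdom[m])
  keep <- !is.na(index_series$label) & !is.na(frac)
  lab <- factor(as.character(index_series$label[keep]),
                levels = c("NON_BLOOM", "PRE_ALERT", "ACTIVE_BLOOM"))
  frac <- frac[keep]
  tibble::tibble(
    label = levels(lab),
    n = as.integer(table(lab)),
    mean_contribution_pct = as.numeric(tapply(100 * frac, lab, mean))
  )
}

#' Match field samples to satellite observations
#'
#' Field campaigns rarely coincide with a valid satellite overpass; each
#' field sample is paired with satellite data from a window around its
#' date, either the nearest valid (pair-complete) satellite day (ties go
#' to the earlier day) or the mean of all valid days in the window
#' (composite mode, mirroring multi-day satellite composites).
#'
#' @param field Tibble with `station`, `date`, `aphy_field`, `adcdom_field`
#'   (m^-1, > 0).
#' @param series Satellite [pixel_series()].
#' @param window_days Half-width of the matchup window in days (default 8).
#' @param mode `"nearest"` or `"composite"`.
#' @return Tibble: field columns plus `aphy_sat`, `adcdom_sat`,
#'   `matchup_lag_days` (`NA` in composite mode), rows without any valid
#'   satellite day dropped.
#' @export
match_field_satellite <- function(field, series, window_days = 8,
                                  mode = c("nearest", "composite")) {
  mode <- match.arg(mode)
  sat <- series[pair_complete(series), ]
  rows <- lapply(seq_len(nrow(field)), function(i) {
    d <- as.Date(field$date[i])
    lag <- as.integer(sat$date - d)
    in_win <- abs(lag) <= window_days
    if (!any(in_win)) return(NULL)
    if (mode == "nearest") {
      j <- which(in_win)[order(abs(lag[in_win]), lag[in_win])][1]
      ap <- sat$aphy[j]; ad <- sat$adcdom[j]; lg <- lag[j]
    } else {
      ap <- mean(sat$aphy[in_win]); ad <- mean(sat$adcdom[in_win]); lg <- NA_integer_
    }
    tibble::tibble(station = field$station[i], date = d,
                   aphy_field = field$aphy_field[i], adcdom_field = field$adcdom_field[i],
                   aphy_sat = ap, adcdom_sat = ad, matchup_lag_days = lg)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("match_field_satellite: no field sample has satellite data in window",
                         call. = FALSE)
  out
}

#' Spearman rank validation of satellite against field data
#'
#' Rank correlation with average ranks for ties and a two-sided
#' significance test; requires at least 4 matched pairs for the test to be
#' meaningful.
#'
#' @param x,y Matched numeric vectors (e.g. field and satellite absorption).
#' @return List: `rho`, `p_value`, `n`.
#' @export
#' @examples
#' spearman_validation(1:6, c(2, 1, 4, 3, 6, 5))  # rho 0.771
spearman_validation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("spearman_validation: need >= 4 matched pairs", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Validate both absorption coefficients on a matchup table
#'
#' @param matched Tibble from [match_field_satellite()].
#' @return Tibble with one row per coefficient: `variable`, `rho`,
#'   `p_value`, `n`.
#' @export
validate_absorption <- function(matched) {
  a <- spearman_validation(matched$aphy_field, matched$aphy_sat)
  d <- spearman_validation(matched$adcdom_field, matched$adcdom_sat)
  tibble::tibble(variable = c("aphy", "adcdom"),
                 rho = c(a$rho, d$rho),
                 p_value = c(a$p_value, d$p_value),
                 n = c(a$n, d$n))
}
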