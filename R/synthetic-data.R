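#' Describe an injected bloom event
#'
#' Bloom events are injected into synthetic series as additive anomalies on
#' the standardized (SD-unit) scale, so an amplitude of 4 means the affected
#' coefficient sits 4 climatological standard deviations above its monthly
#' mean before daily noise. `target` selects which coefficient is elevated:
#' a phytoplankton bloom raises `aphy`, a CDOM/detritus plume raises
#' `adcdom`, and `"both"` emulates a mixed event.
#'
#' @param start_date First day of the event (`Date` or ISO string).
#' @param duration_days Length in consecutive calendar days (>= 1).
#' @param amplitude_sd Anomaly amplitude in climatology SD units (>= 0).
#' @param target `"both"`, `"phyto"` or `"cdom"`.
#' @return A `bloom_event` list.
#' @export
#' @examples
#' bloom_event("2005-05-10", duration_days = 3, amplitude_sd = 4)
bloom_event <- function(start_date, duration_days, amplitude_sd,
                        target = c("both", "phyto", "cdom")) {
  target <- match.arg(target)
  start_date <- as.Date(start_date)
  if (is.na(start_date)) stop("bloom_event: unparseable start_date", call. = FALSE)
  duration_days <- as.integer(duration_days)
  if (duration_days < 1) stop("bloom_event: duration_days must be >= 1", call. = FALSE)
  if (amplitude_sd < 0) stop("bloom_event: amplitude_sd must be >= 0", call. = FALSE)
  structure(list(start_date = start_date, duration_days = duration_days,
                 amplitude_sd = amplitude_sd, target = target),
            class = "bloom_event")
}

#' Configuration of the synthetic absorption-series generator
#'
#' The generator emulates the statistical regime of daily Level-2 ocean-color
#' extractions at a coastal monitoring point: correlated bivariate absorption
#' pairs with month-specific means, heavy cloud-gap missingness, and optional
#' injected bloom events with recorded ground truth.
#'
#' Defaults mirror a cloudy temperate bay monitored in late spring:
#' fourteen years (2003--2016) of May--June days, typical coastal magnitudes
#' of 0.05 m^-1 (`aphy`) and 0.04 m^-1 (`adcdom`) at the blue reference band,
#' a coefficient of variation of 0.4, a pair correlation of 0.6, and a daily
#' cloud-gap probability of 0.7 (so roughly a quarter to a third of possible
#' days are observed).
#'
#' @param years Integer vector of years to simulate.
#' @param months Integer vector of month numbers (1--12); must be non-empty.
#' @param base_mean_aphy,base_mean_adcdom Monthly mean absorption (m^-1, > 0).
#' @param month_scale Optional named numeric vector of per-month multipliers
#'   applied to both base means (names = month numbers), giving the months
#'   distinct climatologies; months absent from it get multiplier 1.
#' @param cv Coefficient of variation of daily values about the month mean (> 0).
#' @param rho Target Pearson correlation of the daily pair, in \[-1, 1\].
#' @param missing_prob Daily cloud-gap probability, in \[0, 1).
#' @param missing_mode `"iid"` for independent daily gaps, `"spells"` for
#'   geometric cloudy spells (multi-day gaps, reproducing two-week outages).
#' @param mean_spell_length Mean cloudy-spell length in days (spells mode).
#' @param bloom_events List of [bloom_event()]s. Events overlapping in time
#'   with different targets are rejected; same-target overlaps add.
#' @param point_id Point identifier stamped on the series.
#' @param seed Integer RNG seed; the same seed and config give bit-identical
#'   output.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(years = 2003:2016, months = 5:6,
                         base_mean_aphy = 0.05, base_mean_adcdom = 0.04,
                         month_scale = NULL,
                         cv = 0.4, rho = 0.6,
                         missing_prob = 0.7,
                         missing_mode = c("iid", "spells"),
                         mean_spell_length = 3,
                         bloom_events = list(),
                         point_id = "P1", seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  if (length(months) == 0) stop("synth_config: months must be non-empty", call. = FALSE)
  if (!all(months %in% 1:12)) stop("synth_config: months must be in 1..12", call. = FALSE)
  if (base_mean_aphy <= 0 || base_mean_adcdom <= 0) {
    stop("synth_config: base means must be > 0", call. = FALSE)
  }
  if (cv <= 0) stop("synth_config: cv must be > 0", call. = FALSE)
  if (rho < -1 || rho > 1) stop("synth_config: rho must be in [-1, 1]", call. = FALSE)
  if (missing_prob < 0 || missing_prob >= 1) {
    stop("synth_config: missing_prob must be in [0, 1)", call. = FALSE)
  }
  if (mean_spell_length < 1) stop("synth_config: mean_spell_length must be >= 1", call. = FALSE)
  for (ev in bloom_events) {
    if (!inherits(ev, "bloom_event")) stop("synth_config: bloom_events must be bloom_event objects", call. = FALSE)
  }
  check_event_overlap(bloom_events)
  structure(list(
    years = as.integer(years), months = as.integer(months),
    base_mean_aphy = base_mean_aphy, base_mean_adcdom = base_mean_adcdom,
    month_scale = month_scale, cv = cv, rho = rho,
    missing_prob = missing_prob, missing_mode = missing_mode,
    mean_spell_length = mean_spell_length,
    bloom_events = bloom_events, point_id = point_id, seed = as.integer(seed)
  ), class = "synth_config")
}

event_dates <- function(ev) ev$start_date + seq_len(ev$duration_days) - 1L

check_event_overlap <- function(events) {
  if (length(events) < 2) return(invisible(TRUE))
  for (i in seq_along(events)) {
    for (j in seq_len(i - 1)) {
      shared <- intersect(event_dates(events[[i]]), event_dates(events[[j]]))
      if (length(shared) > 0 && events[[i]]$target != events[[j]]$target) {
        stop("synth_config: bloom events with conflicting targets overlap on ",
             paste(as.Date(shared, origin = "1970-01-01"), collapse = ", "),
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Load a generator configuration from a YAML file
#'
#' Scalar fields map one-to-one onto [synth_config()] arguments; bloom
#' events are given as a list of maps with keys `start_date`,
#' `duration_days`, `amplitude_sd`, `target`.
#'
#' @param path YAML file path.
#' @return A `synth_config`.
#' @export
synth_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$bloom_events)) {
    raw$bloom_events <- lapply(raw$bloom_events, function(e) {
      bloom_event(e$start_date, e$duration_days, e$amplitude_sd,
                  target = if (is.null(e$target)) "both" else e$target)
    })
  }
  if (!is.null(raw$years) && length(raw$years) == 2) raw$years <- raw$years[1]:raw$years[2]
  do.call(synth_config, raw)
}

month_mean <- function(config, var, month) {
  base <- if (var == "aphy") config$base_mean_aphy else config$base_mean_adcdom
  sc <- config$month_scale
  if (!is.null(sc) && as.character(month) %in% names(sc)) base * sc[[as.character(month)]] else base
}

all_config_dates <- function(config) {
  days <- lapply(config$years, function(y) {
    first <- as.Date(sprintf("%d-01-01", y))
    d <- seq(first, as.Date(sprintf("%d-12-31", y)), by = "day")
    d[month_of(d) %in% config$months]
  })
  sort(do.call(c, days))
}

#' Simulate a daily absorption series with ground truth
#'
#' Pairs are drawn on the standardized (Z) scale from a bivariate normal
#' with unit variances and correlation `rho`, bloom anomalies are added on
#' that scale, and values are then mapped to the absorption scale as
#' `mean * (1 + cv * z)`, floored at 1e-5 m^-1 since absorption is
#' physically positive. Cloud gaps blank both coefficients of a day.
#'
#' @param config A [synth_config()].
#' @return A list with elements `series` (a [pixel_series()] over every
#'   calendar day of the configured months/years, `NA` on gap days) and
#'   `truth` (a tibble of injected bloom days: `date`, `amplitude_sd`,
#'   `target`, restricted to days the config actually generates).
#' @export
#' @examples
#' sim <- simulate_series(synth_config(years = 2003:2004, missing_prob = 0, seed = 7))
#' nrow(sim$series)  # every May/June day of 2003-2004
simulate_series <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  dates <- all_config_dates(config)
  n <- length(dates)
  set.seed(config$seed)

  # correlated standard-normal pair via Cholesky
  z1 <- stats::rnorm(n)
  e  <- stats::rnorm(n)
  z2 <- config$rho * z1 + sqrt(max(0, 1 - config$rho^2)) * e

  miss <- simulate_missing(config, n)

  truth <- tibble::tibble(date = as.Date(character()), amplitude_sd = numeric(),
                          target = character())
  for (ev in config$bloom_events) {
    ed <- event_dates(ev)
    idx <- match(ed, dates)
    hit <- !is.na(idx)
    if (ev$target %in% c("both", "phyto")) z1[idx[hit]] <- z1[idx[hit]] + ev$amplitude_sd
    if (ev$target %in% c("both", "cdom"))  z2[idx[hit]] <- z2[idx[hit]] + ev$amplitude_sd
    truth <- rbind(truth, tibble::tibble(date = ed[hit], amplitude_sd = ev$amplitude_sd,
                                         target = ev$target))
  }
  truth <- truth[order(truth$date), ]

  mo <- month_of(dates)
  m1 <- vapply(mo, function(m) month_mean(config, "aphy", m), numeric(1))
  m2 <- vapply(mo, function(m) month_mean(config, "adcdom", m), numeric(1))
  aphy   <- pmax(m1 * (1 + config$cv * z1), 1e-5)
  adcdom <- pmax(m2 * (1 + config$cv * z2), 1e-5)
  aphy[miss] <- NA_real_
  adcdom[miss] <- NA_real_

  series <- pixel_series(dates, aphy, adcdom, point_id = config$point_id,
                         source = sprintf("simulate_series(seed=%d)", config$seed))
  list(series = series, truth = truth)
}

simulate_missing <- function(config, n) {
  p <- config$missing_prob
  if (p == 0) return(rep(FALSE, n))
  if (config$missing_mode == "iid") return(stats::runif(n) < p)
  # alternating clear/cloudy spells with geometric lengths whose stationary
  # cloudy fraction equals missing_prob
  mean_cloudy <- config$mean_spell_length
  mean_clear <- mean_cloudy * (1 - p) / p
  miss <- logical(n)
  i <- 1L
  cloudy <- stats::runif(1) < p
  while (i <= n) {
    len <- 1L + stats::rgeom(1, 1 / (if (cloudy) mean_cloudy else max(mean_clear, 1)))
    j <- min(n, i + len - 1L)
    miss[i:j] <- cloudy
    i <- j + 1L
    cloudy <- !cloudy
  }
  miss
}

#' Simulate a single-date gridded granule
#'
#' Generates one 2-D field per coefficient around the configured base means,
#' optionally elevating the centre 3x3 patch (`center_bias`, in SD units) to
#' emulate a bloom patch, and optionally blanking pixels at the config's
#' `missing_prob`. The realized centre-patch means are recorded in the
#' grid's `meta` so window-extraction can be checked against an arithmetic
#' oracle.
#'
#' @param config A [synth_config()]; its first month's means, `cv` and
#'   `missing_prob` shape the field.
#' @param nrows,ncols Grid dimensions (>= 3).
#' @param center_bias Additive anomaly (SD units) on the centre 3x3 patch.
#' @param date Granule date.
#' @return An `iop_grid`: list with matrices `aphy`, `adcdom`, the `date`,
#'   and `meta$center_mean_aphy` / `meta$center_mean_adcdom` (mean over the
#'   valid pixels of the centre 3x3 patch, `NA` if none).
#' @export
simulate_grid <- function(config, nrows = 11, ncols = 11, center_bias = 0,
                          date = as.Date(sprintf("%d-%02d-15", config$years[1], config$months[1]))) {
  stopifnot(inherits(config, "synth_config"))
  if (nrows < 3 || ncols < 3) stop("simulate_grid: grid must be at least 3x3", call. = FALSE)
  set.seed(config$seed)
  mo <- config$months[1]
  n <- nrows * ncols
  z1 <- matrix(stats::rnorm(n), nrows, ncols)
  e  <- matrix(stats::rnorm(n), nrows, ncols)
  z2 <- config$rho * z1 + sqrt(max(0, 1 - config$rho^2)) * e
  cr <- (floor((nrows + 1) / 2) - 1):(floor((nrows + 1) / 2) + 1)
  cc <- (floor((ncols + 1) / 2) - 1):(floor((ncols + 1) / 2) + 1)
  z1[cr, cc] <- z1[cr, cc] + center_bias
  z2[cr, cc] <- z2[cr, cc] + center_bias
  aphy   <- pmax(month_mean(config, "aphy", mo)   * (1 + config$cv * z1), 1e-5)
  adcdom <- pmax(month_mean(config, "adcdom", mo) * (1 + config$cv * z2), 1e-5)
  if (config$missing_prob > 0) {
    miss <- matrix(stats::runif(n) < config$missing_prob, nrows, ncols)
    aphy[miss] <- NA_real_
    adcdom[miss] <- NA_real_
  }
  patch_mean <- function(m) {
    v <- m[cr, cc]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  structure(list(
    aphy = aphy, adcdom = adcdom, date = as.Date(date),
    meta = list(center_row = cr[2], center_col = cc[2],
                center_mean_aphy = patch_mean(aphy),
                center_mean_adcdom = patch_mean(adcdom))
  ), class = "iop_grid")
}
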