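#' Climatological standardization (Z transformation)
#'
#' Converts an absorption value to a standardized anomaly in units of
#' climatological standard deviations: `Z = (x - mean) / sd`, where mean
#' and sd are the pooled month-across-years statistics of the site.
#'
#' @param x Value(s) to standardize (m^-1); `NA` passes through.
#' @param mean Climatological mean (m^-1).
#' @param sd Climatological standard deviation (m^-1, > 0).
#' @return Dimensionless standardized anomaly.
#' @export
standardize <- function(x, mean, sd) {
  if (any(sd <= 0)) stop("standardize: sd must be > 0", call. = FALSE)
  (x - mean) / sd
}

#' Fit the monthly climatology of a pixel series
#'
#' Pools all days of one calendar month across the fitting years (e.g. all
#' May days of 2003--2016 as a single sample) and returns per-coefficient
#' means and sample (n-1) standard deviations. Each coefficient is averaged
#' over all of its own valid days; `n_obs` counts the days where both are
#' present (the days the bivariate index will exist on). With real QC the
#' two sets can differ slightly, which is why frozen baselines are small
#' but not always exactly zero.
#'
#' @param series A [pixel_series()].
#' @param month Calendar month number (1--12).
#' @param fit_years Years to pool; `NULL` = every year in the series.
#' @return A `climatology` list: `point_id`, `month`, `mean_aphy`,
#'   `sd_aphy`, `mean_adcdom`, `sd_adcdom`, `n_obs` (paired days),
#'   `n_aphy`, `n_adcdom`, `fit_years`.
#' @export
fit_climatology <- function(series, month, fit_years = NULL) {
  sel <- month_of(series$date) == month
  if (!is.null(fit_years)) sel <- sel & year_of(series$date) %in% fit_years
  x <- series[sel, ]
  pid <- if (nrow(series)) series$point_id[1] else "?"
  n_pair <- sum(!is.na(x$aphy) & !is.na(x$adcdom))
  if (n_pair < 2) {
    stop(sprintf("fit_climatology: point %s month %d: need >= 2 paired observations, have %d",
                 pid, month, n_pair), call. = FALSE)
  }
  ap <- x$aphy[!is.na(x$aphy)]
  ad <- x$adcdom[!is.na(x$adcdom)]
  out <- list(
    point_id = pid, month = as.integer(month),
    mean_aphy = mean(ap), sd_aphy = stats::sd(ap),
    mean_adcdom = mean(ad), sd_adcdom = stats::sd(ad),
    n_obs = n_pair, n_aphy = length(ap), n_adcdom = length(ad),
    fit_years = if (is.null(fit_years)) sort(unique(year_of(x$date))) else as.integer(fit_years)
  )
  if (out$sd_aphy <= 0 || out$sd_adcdom <= 0) {
    stop(sprintf("fit_climatology: point %s month %d: sd <= 0 (constant series)", pid, month),
         call. = FALSE)
  }
  structure(out, class = "climatology")
}

#' Fit the first standardized orthogonal empirical function (SOEF)
#'
#' Eigen-decomposes the 2x2 sample correlation matrix of the standardized
#' coefficient pair. The leading unit eigenvector supplies the index
#' weights (b11 on Z_aphy, b12 on Z_adcdom); eigenvalues satisfy
#' lambda1 + lambda2 = 2 and, for sample correlation r, lambda1 = 1 + |r|.
#' The eigenvector is oriented so the loading on the phytoplankton
#' coefficient is non-negative (b11 >= 0): higher phytoplankton absorption
#' must raise the index, otherwise bloom and non-bloom flip. At r = 0 the
#' decomposition is degenerate (lambda1 = lambda2) and the model falls
#' back to b = (1, 0) with `degenerate = TRUE`.
#'
#' @param z_aphy,z_adcdom Standardized pairs (equal length, no `NA` among
#'   the used pairs; incomplete pairs are dropped).
#' @return A `soef_model`: `b` (named `b11`, `b12`, unit length),
#'   `eigenvalues` (descending), `rho` (sample correlation), `n`,
#'   `degenerate`.
#' @export
fit_soef <- function(z_aphy, z_adcdom) {
  keep <- !is.na(z_aphy) & !is.na(z_adcdom)
  z1 <- z_aphy[keep]; z2 <- z_adcdom[keep]
  if (length(z1) < 2) stop("fit_soef: need >= 2 complete pairs", call. = FALSE)
  if (stats::sd(z1) == 0 || stats::sd(z2) == 0) {
    stop("fit_soef: standardized series must be non-constant", call. = FALSE)
  }
  r <- stats::cor(z1, z2)
  M <- matrix(c(1, r, r, 1), 2, 2)
  ev <- eigen(M, symmetric = TRUE)
  b <- ev$vectors[, 1]
  degenerate <- abs(ev$values[1] - ev$values[2]) < 1e-12
  if (degenerate) {
    b <- c(1, 0)
  } else if (b[1] < 0) {
    b <- -b
  }
  structure(list(b = c(b11 = b[1], b12 = b[2]),
                 eigenvalues = ev$values, rho = r, n = length(z1),
                 degenerate = degenerate),
            class = "soef_model")
}

#' Daily IOP index from a standardized pair
#'
#' The satellite IOP index of a day is the projection of its standardized
#' coefficient pair onto the first SOEF eigenvector:
#' `index = b11 * Z_aphy + b12 * Z_adcdom`. A day missing either Z gets a
#' missing index (no error): cloud gaps are normal operating conditions.
#'
#' @param z_aphy,z_adcdom Standardized values (vectors ok).
#' @param soef A `soef_model` from [fit_soef()].
#' @return Dimensionless index value(s), `NA` where a Z is missing.
#' @export
compute_index <- function(z_aphy, z_adcdom, soef) {
  stopifnot(inherits(soef, "soef_model"))
  soef$b[["b11"]] * z_aphy + soef$b[["b12"]] * z_adcdom
}

#' Active-bloom threshold from the normal inverse CDF
#'
#' Under standardization, daily index values behave like standardized
#' anomalies; the two-sided normal quantile at the chosen confidence level
#' bounds the values attributable to noise. At 90% confidence the quantile
#' is 1.6449, i.e. 1.6 SD at one decimal — the active-bloom threshold.
#'
#' @param confidence Two-sided confidence level in (0, 1).
#' @return Threshold in SD units: `qnorm((1 + confidence) / 2)`.
#' @export
#' @examples
#' round(icdf_threshold(0.90), 1)  # 1.6
icdf_threshold <- function(confidence) {
  if (confidence <= 0 || confidence >= 1) {
    stop("icdf_threshold: confidence must be in (0, 1)", call. = FALSE)
  }
  stats::qnorm((1 + confidence) / 2)
}

#' Classification thresholds for index values
#'
#' @param pre_alert Lower bound of the pre-alert band (SD units).
#' @param confidence Confidence level from which the active-bloom threshold
#'   is derived (rounded to one decimal), unless `active` is given.
#' @param active Active-bloom threshold (SD units); default
#'   `round(icdf_threshold(confidence), 1)`.
#' @return A `class_thresholds` list.
#' @export
class_thresholds <- function(pre_alert = 1.0, confidence = 0.90,
                             active = round(icdf_threshold(confidence), 1)) {
  if (pre_alert <= 0 || active <= pre_alert) {
    stop("class_thresholds: need 0 < pre_alert < active", call. = FALSE)
  }
  structure(list(pre_alert = pre_alert, active = active, confidence = confidence),
            class = "class_thresholds")
}

#' Classify index values into bloom states
#'
#' Left-closed bands so every finite value gets exactly one label:
#' index < `pre_alert` is NON_BLOOM (average conditions; strongly negative
#' anomalies, index <= -pre_alert, are still NON_BLOOM — see
#' [negative_anomaly()]); `pre_alert` <= index < `active` is PRE_ALERT
#' (growing or decaying bloom); index >= `active` is ACTIVE_BLOOM.
#'
#' @param index Numeric index value(s); `NA` stays `NA`.
#' @param thresholds A [class_thresholds()].
#' @return Ordered factor with levels NON_BLOOM < PRE_ALERT < ACTIVE_BLOOM.
#' @export
classify <- function(index, thresholds = class_thresholds()) {
  stopifnot(inherits(thresholds, "class_thresholds"))
  lab <- ifelse(index >= thresholds$active, "ACTIVE_BLOOM",
         ifelse(index >= thresholds$pre_alert, "PRE_ALERT", "NON_BLOOM"))
  factor(lab, levels = c("NON_BLOOM", "PRE_ALERT", "ACTIVE_BLOOM"), ordered = TRUE)
}

#' Flag strongly negative anomalies
#'
#' Values at or below minus the pre-alert threshold are anomalously clear
#' water; they classify as NON_BLOOM but are flagged for interpretation.
#'
#' @inheritParams classify
#' @return Logical vector.
#' @export
negative_anomaly <- function(index, thresholds = class_thresholds()) {
  !is.na(index) & index <= -thresholds$pre_alert
}

#' Fit the per-site monthly baseline model
#'
#' Chains the whole fitting procedure on one calendar month of a series:
#' monthly climatology -> standardization -> first SOEF eigenvector ->
#' daily index, and records the mean index over the fitting period as the
#' baseline. On a gap-free fit the baseline is exactly 0 by construction
#' (each standardized coefficient has mean zero over its fitting set, and
#' the index is a fixed linear combination); when QC leaves days with only
#' one valid coefficient, the per-coefficient standardization sets and the
#' paired index set differ slightly and the baseline takes small nonzero
#' magnitudes of order 1e-3.
#'
#' The fitted model is frozen: new data are scored against it with
#' [compute_index_series()] without refitting; refits are an explicit,
#' deliberate act as the archive grows.
#'
#' @inheritParams fit_climatology
#' @param thresholds A [class_thresholds()].
#' @return An `iop_baseline`: `climatology`, `soef`, `baseline_index`,
#'   `fit_period` (year range), `thresholds`.
#' @export
fit_baseline <- function(series, month, fit_years = NULL,
                         thresholds = class_thresholds()) {
  clim <- fit_climatology(series, month, fit_years)
  sel <- month_of(series$date) == month & pair_complete(series) &
    year_of(series$date) %in% clim$fit_years
  x <- series[sel, ]
  z1 <- standardize(x$aphy, clim$mean_aphy, clim$sd_aphy)
  z2 <- standardize(x$adcdom, clim$mean_adcdom, clim$sd_adcdom)
  soef <- fit_soef(z1, z2)
  idx <- compute_index(z1, z2, soef)
  structure(list(
    climatology = clim, soef = soef,
    baseline_index = mean(idx),
    fit_period = range(clim$fit_years),
    thresholds = thresholds
  ), class = "iop_baseline")
}

#' Score a series against a frozen baseline model
#'
#' Standardizes every day of the baseline's calendar month with the frozen
#' climatology, projects with the frozen eigenvector, and classifies. Days
#' missing either coefficient get a missing index and label.
#'
#' @param series A [pixel_series()] (fitting data or new data).
#' @param baseline An `iop_baseline` from [fit_baseline()].
#' @param years Optional year filter.
#' @return An index series: tibble with `date`, `point_id`, `index`,
#'   `label` (ordered factor, `NA` on gap days), `negative_anomaly`.
#' @export
compute_index_series <- function(series, baseline, years = NULL) {
  stopifnot(inherits(baseline, "iop_baseline"))
  clim <- baseline$climatology
  sel <- month_of(series$date) == clim$month
  if (!is.null(years)) sel <- sel & year_of(series$date) %in% years
  x <- series[sel, ]
  ok <- pair_complete(x)
  z1 <- ifelse(ok, standardize(x$aphy, clim$mean_aphy, clim$sd_aphy), NA_real_)
  z2 <- ifelse(ok, standardize(x$adcdom, clim$mean_adcdom, clim$sd_adcdom), NA_real_)
  idx <- compute_index(z1, z2, baseline$soef)
  tibble::tibble(
    date = x$date, point_id = x$point_id,
    index = idx,
    label = classify(idx, baseline$thresholds),
    negative_anomaly = negative_anomaly(idx, baseline$thresholds)
  )
}

#' Serialize / restore a baseline model as JSON
#'
#' All floats are written at full double precision; the fitting period and
#' sample size travel with the model for provenance.
#'
#' @param baseline An `iop_baseline`.
#' @param path JSON file path.
#' @return `path` (write) or an `iop_baseline` (read).
#' @export
write_baseline_json <- function(baseline, path) {
  stopifnot(inherits(baseline, "iop_baseline"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_baseline_json requires the jsonlite package", call. = FALSE)
  }
  obj <- list(
    climatology = unclass(baseline$climatology),
    soef = unclass(baseline$soef),
    baseline_index = baseline$baseline_index,
    fit_period = baseline$fit_period,
    thresholds = unclass(baseline$thresholds)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_baseline_json
#' @export
read_baseline_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("read_baseline_json requires the jsonlite package", call. = FALSE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  soef <- obj$soef
  soef$b <- c(b11 = soef$b[[1]], b12 = soef$b[[2]])
  structure(list(
    climatology = structure(as.list(obj$climatology), class = "climatology"),
    soef = structure(soef, class = "soef_model"),
    baseline_index = obj$baseline_index,
    fit_period = obj$fit_period,
    thresholds = structure(as.list(obj$thresholds), class = "class_thresholds")
  ), class = "iop_baseline")
}
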