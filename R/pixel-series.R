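#' Daily absorption-coefficient record for one monitoring point
#'
#' A pixel series is the basic container of the pipeline: one row per
#' calendar day with the two absorption coefficients extracted at a fixed
#' monitoring point — phytoplankton absorption (`aphy`) and detritus plus
#' colored-dissolved-organic-matter absorption (`adcdom`), both in m^-1.
#' Cloud-covered days carry `NA` in one or both coefficients.
#'
#' @param dates Vector of `Date`s (coerced with [as.Date()]); must be unique.
#' @param aphy,adcdom Numeric absorption coefficients (m^-1); `NA` = missing.
#'   Non-missing values must be strictly positive.
#' @param point_id Identifier of the monitoring point.
#' @param source Free-text provenance (file name, generator call, ...).
#'
#' @return A [tibble::tibble] with columns `date`, `point_id`, `aphy`,
#'   `adcdom`, sorted by date, with attribute `source`.
#' @export
#' @examples
#' pixel_series(as.Date("2017-05-01") + 0:2, c(0.05, NA, 0.07), c(0.04, NA, 0.05))
pixel_series <- function(dates, aphy, adcdom, point_id = "P1", source = "unknown") {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("pixel_series: unparseable dates", call. = FALSE)
  if (anyDuplicated(dates)) stop("pixel_series: duplicate dates", call. = FALSE)
  n <- length(dates)
  aphy <- as.numeric(aphy)
  adcdom <- as.numeric(adcdom)
  if (length(aphy) != n || length(adcdom) != n) {
    stop("pixel_series: dates, aphy and adcdom must have equal length", call. = FALSE)
  }
  if (any(aphy <= 0, na.rm = TRUE) || any(adcdom <= 0, na.rm = TRUE)) {
    stop("pixel_series: absorption coefficients must be > 0 (use NA for missing)",
         call. = FALSE)
  }
  ord <- order(dates)
  out <- tibble::tibble(
    date = dates[ord],
    point_id = as.character(point_id),
    aphy = aphy[ord],
    adcdom = adcdom[ord]
  )
  attr(out, "source") <- source
  out
}

#' Which days carry both coefficients?
#'
#' The bivariate index needs both standardized coefficients on a day; a day
#' with only one valid coefficient is kept in the raw series for QC but is
#' treated as missing by the index machinery.
#'
#' @param series A pixel series (see [pixel_series()]).
#' @return Logical vector, `TRUE` where both `aphy` and `adcdom` are present.
#' @export
pair_complete <- function(series) {
  !is.na(series$aphy) & !is.na(series$adcdom)
}

month_of <- function(d) as.integer(format(as.Date(d), "%m"))
year_of  <- function(d) as.integer(format(as.Date(d), "%Y"))

#' Write a pixel series to CSV
#'
#' Plain CSV dialect: header row, comma separators, ISO-8601 dates, empty
#' string for missing values.
#'
#' @param series A pixel series.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  df <- data.frame(
    date = format(series$date, "%Y-%m-%d"),
    point_id = series$point_id,
    aphy = ifelse(is.na(series$aphy), "", format(series$aphy, digits = 17, trim = TRUE, scientific = FALSE)),
    adcdom = ifelse(is.na(series$adcdom), "", format(series$adcdom, digits = 17, trim = TRUE, scientific = FALSE)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pixel series from CSV, with row-level QC
#'
#' Rows violating the series invariants (unparseable date, non-positive
#' absorption, duplicate date) are dropped and counted; set `strict = TRUE`
#' to raise instead. The QC tally is attached as attribute `"qc"`:
#' a list with `n_read`, `n_kept`, `n_dropped` and a per-reason breakdown.
#'
#' @param path CSV path (columns `date`, `point_id`, `aphy`, `adcdom`).
#' @param strict Raise an error on any invalid row instead of dropping it.
#' @return A pixel series with attribute `qc`.
#' @export
read_series_csv <- function(path, strict = FALSE) {
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("date", "point_id", "aphy", "adcdom")
  if (!all(need %in% names(raw))) {
    stop("read_series_csv: missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  aphy <- num(raw$aphy)
  adcdom <- num(raw$adcdom)

  bad_date <- is.na(dates)
  bad_neg  <- (!is.na(aphy) & aphy <= 0) | (!is.na(adcdom) & adcdom <= 0)
  dup      <- duplicated(dates) & !bad_date
  drop <- bad_date | bad_neg | dup
  qc <- list(
    n_read = nrow(raw),
    n_kept = sum(!drop),
    n_dropped = sum(drop),
    reasons = c(unparseable_date = sum(bad_date),
                nonpositive_value = sum(bad_neg & !bad_date),
                duplicate_date = sum(dup & !bad_neg))
  )
  if (strict && qc$n_dropped > 0) {
    stop("read_series_csv: ", qc$n_dropped, " invalid row(s) in ", path, call. = FALSE)
  }
  keep <- !drop
  out <- pixel_series(dates[keep], aphy[keep], adcdom[keep],
                      point_id = if (qc$n_kept > 0) raw$point_id[keep][1] else "P1",
                      source = path)
  attr(out, "qc") <- qc
  out
}
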