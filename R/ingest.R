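#' Window-averaged pixel extraction
#'
#' Point values are extracted from gridded granules as the arithmetic mean
#' of an odd-sized pixel window centred on the pixel of interest (default
#' 3x3, matching daily 1-km ocean-color practice). Fill pixels are ignored;
#' if fewer than `min_valid` valid pixels remain, the result is `NA`.
#' Windows are clipped at grid boundaries, so near-edge (coastal) pixels
#' average over the available cells only.
#'
#' @param grid Numeric matrix (one variable's field); `NA` = fill.
#' @param row,col Centre pixel indices.
#' @param window Odd window side length (default 3).
#' @param min_valid Minimum number of valid pixels required (default 1).
#' @return Scalar mean, or `NA_real_` if fewer than `min_valid` pixels valid.
#' @export
#' @examples
#' window_average(matrix(0.05, 5, 5), 3, 3)  # 0.05
window_average <- function(grid, row, col, window = 3, min_valid = 1) {
  stopifnot(is.matrix(grid))
  if (window %% 2 != 1 || window < 1) {
    stop("window_average: window must be odd and >= 1", call. = FALSE)
  }
  if (window > nrow(grid) || window > ncol(grid)) {
    stop("window_average: window larger than grid", call. = FALSE)
  }
  if (row < 1 || row > nrow(grid) || col < 1 || col > ncol(grid)) {
    stop("window_average: centre pixel outside grid", call. = FALSE)
  }
  h <- (window - 1) / 2
  rr <- max(1, row - h):min(nrow(grid), row + h)
  cc <- max(1, col - h):min(ncol(grid), col + h)
  v <- grid[rr, cc]
  v <- v[!is.na(v)]
  if (length(v) < min_valid) NA_real_ else mean(v)
}

#' Extract both coefficients at a point from one granule
#'
#' @param granule An `iop_grid` (see [simulate_grid()] / [read_granule()]).
#' @inheritParams window_average
#' @return Named numeric vector `c(aphy = , adcdom = )`; `NA` where the
#'   window had too few valid pixels.
#' @export
extract_point <- function(granule, row, col, window = 3, min_valid = 1) {
  stopifnot(inherits(granule, "iop_grid"))
  c(aphy   = window_average(granule$aphy,   row, col, window, min_valid),
    adcdom = window_average(granule$adcdom, row, col, window, min_valid))
}

#' Write / read a gridded granule as plain-text CSV
#'
#' Granules are stored in a long CSV format (`row`, `col`, `aphy`,
#' `adcdom`; empty field = fill) preceded by `#`-comment header lines
#' carrying the date and the grid dimensions. This keeps fixtures
#' text-only and diffable.
#'
#' @param granule An `iop_grid`.
#' @param path File path.
#' @return `path` (write) or an `iop_grid` (read).
#' @export
write_granule <- function(granule, path) {
  stopifnot(inherits(granule, "iop_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# date=%s", format(granule$date, "%Y-%m-%d")),
    sprintf("# nrows=%d ncols=%d", nrow(granule$aphy), ncol(granule$aphy))
  ), con)
  idx <- expand.grid(row = seq_len(nrow(granule$aphy)), col = seq_len(ncol(granule$aphy)))
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 17, trim = TRUE, scientific = FALSE))
  df <- data.frame(row = idx$row, col = idx$col,
                   aphy = fmt(granule$aphy[cbind(idx$row, idx$col)]),
                   adcdom = fmt(granule$adcdom[cbind(idx$row, idx$col)]))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_granule
#' @export
read_granule <- function(path) {
  hdr <- readLines(path, n = 2)
  date <- as.Date(sub("^# date=", "", hdr[1]))
  dims <- as.integer(strsplit(gsub("[^0-9 ]", "", hdr[2]), " +")[[1]])
  dims <- dims[!is.na(dims)]
  df <- utils::read.csv(path, comment.char = "#")
  num <- function(x) suppressWarnings(as.numeric(x))
  aphy <- matrix(NA_real_, dims[1], dims[2])
  adcdom <- matrix(NA_real_, dims[1], dims[2])
  aphy[cbind(df$row, df$col)] <- num(df$aphy)
  adcdom[cbind(df$row, df$col)] <- num(df$adcdom)
  structure(list(aphy = aphy, adcdom = adcdom, date = date,
                 meta = list()), class = "iop_grid")
}

#' Assemble a multi-date pixel series from granules
#'
#' Runs the window extraction at a fixed pixel over a set of granules and
#' stacks the results into a daily series. When several granules share a
#' date (overlapping passes), their window means are averaged, so the
#' result does not depend on input order.
#'
#' @param granules List of `iop_grid` objects.
#' @inheritParams window_average
#' @param point_id Identifier for the assembled series.
#' @return A [pixel_series()], one row per distinct granule date.
#' @export
assemble <- function(granules, row, col, window = 3, min_valid = 1, point_id = "P1") {
  if (length(granules) == 0) stop("assemble: no granules", call. = FALSE)
  vals <- lapply(granules, extract_point, row = row, col = col,
                 window = window, min_valid = min_valid)
  dates <- as.Date(vapply(granules, function(g) format(g$date, "%Y-%m-%d"), character(1)))
  ap <- vapply(vals, `[[`, numeric(1), "aphy")
  ad <- vapply(vals, `[[`, numeric(1), "adcdom")
  ud <- sort(unique(dates))
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  aphy <- vapply(ud, function(d) mean_or_na(ap[dates == d]), numeric(1))
  adcdom <- vapply(ud, function(d) mean_or_na(ad[dates == d]), numeric(1))
  pixel_series(ud, aphy, adcdom, point_id = point_id,
               source = sprintf("assemble(%d granules)", length(granules)))
}
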