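# In-code fixtures shared across the suite.

# A pixel series straight from vectors of index-like values is awkward to
# build by hand; this helper makes a gap-free series whose standardized
# values are known because mean/sd are taken from the values themselves.
make_series <- function(aphy, adcdom = aphy, start = "2010-05-01", point_id = "P1") {
  pixel_series(as.Date(start) + seq_along(aphy) - 1, aphy, adcdom, point_id = point_id)
}

# Index series (date/point_id/index/label) built directly from index values;
# NA index = cloud-gap day.
make_index_series <- function(index, start = "2017-05-01", point_id = "P1",
                              thresholds = class_thresholds(), dates = NULL) {
  if (is.null(dates)) dates <- as.Date(start) + seq_along(index) - 1
  tibble::tibble(
    date = dates,
    point_id = point_id,
    index = index,
    label = classify(index, thresholds),
    negative_anomaly = negative_anomaly(index, thresholds)
  )
}

# n May days pooled across successive years, so an index series of any
# length stays within a single climatological month.
may_dates <- function(n, first_year = 2003) {
  d <- unlist(lapply(first_year + 0:ceiling(n / 31), function(y) {
    as.character(as.Date(sprintf("%d-05-01", y)) + 0:30)
  }))
  as.Date(d[seq_len(n)])
}

# Independent 2x2 eigensolver via the characteristic polynomial, used as the
# oracle for fit_soef. Returns leading eigenpair with the b11 >= 0 convention.
eig2_oracle <- function(M) {
  tr <- M[1, 1] + M[2, 2]
  det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  # eigenvector from (M - l1 I) v = 0
  if (abs(M[1, 2]) > 1e-300) {
    v <- c(M[1, 2], l1 - M[1, 1])
  } else {
    v <- if (M[1, 1] >= M[2, 2]) c(1, 0) else c(0, 1)
  }
  v <- v / sqrt(sum(v^2))
  if (v[1] < 0) v <- -v
  list(values = c(l1, l2), vector = v)
}

# Spearman rho by the textbook rank formula with average ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# The two-month cloud-gap monitoring narrative: pre-alert observed 24 May,
# 14 missing days (25 May - 7 Jun), pre-alert re-observed 8 Jun, one more
# missing day, non-bloom observed 10-13 Jun, active bloom observed 14 Jun.
narrative_fixture <- function() {
  dates <- seq(as.Date("2017-05-24"), as.Date("2017-06-14"), by = "day")
  index <- rep(NA_real_, length(dates))
  index[dates == as.Date("2017-05-24")] <- 1.3
  index[dates == as.Date("2017-06-08")] <- 1.1
  index[dates %in% (as.Date("2017-06-10") + 0:3)] <- c(0.4, 0.2, 0.3, 0.5)
  index[dates == as.Date("2017-06-14")] <- 2.1
  make_index_series(index, start = dates[1])
}
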