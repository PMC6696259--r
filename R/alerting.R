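#' Conservative gap-holding of daily bloom states
#'
#' Cloud cover interrupts the daily satellite record, sometimes for weeks.
#' The operational rule is conservative: in the absence of new imagery the
#' last observed state is assumed to persist ("the worst scenery remains")
#' until a new observation overrides it. Every calendar day between the
#' first and last date of the input gets an effective state:
#'
#' * `OBSERVED` — the day had a valid index; state is its classification.
#' * `HELD` — no observation; state copied from the last observed day,
#'   with `days_since_obs` counting the age of that information. Held days
#'   never escalate — a held pre-alert stays a pre-alert.
#' * Leading days before any observation get state `UNKNOWN` (assuming
#'   safety with no information would defeat the conservative rule).
#'
#' Holding never expires, but days held longer than `max_hold_days` are
#' flagged `stale` so operators can see how old the standing state is.
#' The default of 14 days is the longest cloud outage the monitoring
#' narrative contemplates.
#'
#' The function is idempotent: an alert log fed back in reproduces itself
#' (held rows are treated as unobserved).
#'
#' @param index_series Tibble with `date` and `label` (from
#'   [compute_index_series()]), or an alert log from a previous call.
#'   Dates absent from the tibble count as missing days.
#' @param max_hold_days Age (days) beyond which a held state is flagged
#'   stale.
#' @return Alert-log tibble, one row per calendar day: `date`, `state`
#'   (`NON_BLOOM`/`PRE_ALERT`/`ACTIVE_BLOOM`/`UNKNOWN`), `provenance`
#'   (`OBSERVED`/`HELD`, `NA` on `UNKNOWN` days), `days_since_obs`
#'   (0 on observed days, `NA` on `UNKNOWN` days), `stale` (logical).
#' @export
hold_state <- function(index_series, max_hold_days = 14) {
  if (max_hold_days < 0) stop("hold_state: max_hold_days must be >= 0", call. = FALSE)
  if (nrow(index_series) == 0) {
    return(tibble::tibble(date = as.Date(character()), state = character(),
                          provenance = character(), days_since_obs = integer(),
                          stale = logical()))
  }
  if ("provenance" %in% names(index_series)) {
    observed_in <- index_series$provenance %in% "OBSERVED"
    lab_in <- ifelse(observed_in, as.character(index_series$state), NA_character_)
  } else {
    observed_in <- !is.na(index_series$label)
    lab_in <- as.character(index_series$label)
  }
  days <- seq(min(index_series$date), max(index_series$date), by = "day")
  m <- match(days, index_series$date)
  lab <- ifelse(!is.na(m) & observed_in[pmax(m, 1)], lab_in[pmax(m, 1)], NA_character_)

  state <- character(length(days))
  prov <- rep(NA_character_, length(days))
  age <- rep(NA_integer_, length(days))
  last <- NA_character_
  last_age <- NA_integer_
  for (i in seq_along(days)) {
    if (!is.na(lab[i])) {
      last <- lab[i]; last_age <- 0L
      state[i] <- last; prov[i] <- "OBSERVED"; age[i] <- 0L
    } else if (!is.na(last)) {
      last_age <- last_age + 1L
      state[i] <- last; prov[i] <- "HELD"; age[i] <- last_age
    } else {
      state[i] <- "UNKNOWN"
    }
  }
  tibble::tibble(date = days, state = state, provenance = prov,
                 days_since_obs = age,
                 stale = !is.na(age) & age > max_hold_days)
}

state_color <- function(state) {
  c(NON_BLOOM = "green", PRE_ALERT = "yellow", ACTIVE_BLOOM = "red",
    UNKNOWN = "gray")[state]
}

#' Daily monitoring report from an alert log
#'
#' One row per calendar day with the effective state, a traffic-light
#' color code (green = non-bloom, yellow = pre-alert, red = active bloom,
#' gray = unknown), the observed index where there was one, and the hold
#' provenance.
#'
#' @param alert_log Tibble from [hold_state()].
#' @param index_series Optional matching index series; supplies the
#'   `index` column for observed days.
#' @return Tibble: `date`, `index`, `state`, `color`, `provenance`,
#'   `days_since_obs`, `stale`.
#' @export
render_report <- function(alert_log, index_series = NULL) {
  idx <- rep(NA_real_, nrow(alert_log))
  if (!is.null(index_series) && nrow(alert_log) > 0) {
    m <- match(alert_log$date, index_series$date)
    idx <- ifelse(alert_log$provenance %in% "OBSERVED" & !is.na(m),
                  index_series$index[pmax(m, 1)], NA_real_)
  }
  tibble::tibble(
    date = alert_log$date, index = idx, state = alert_log$state,
    color = unname(state_color(alert_log$state)),
    provenance = alert_log$provenance,
    days_since_obs = alert_log$days_since_obs, stale = alert_log$stale
  )
}

#' Traffic-light bar chart of a monitoring report
#'
#' Bars show the daily index colored by state (the familiar
#' green/yellow/red monitoring display); held days appear as state-colored
#' rug marks at the axis since they carry no index value.
#'
#' @param report Tibble from [render_report()].
#' @param active_line Draw a horizontal line at this threshold (SD units);
#'   `NULL` to omit.
#' @return A ggplot object.
#' @export
plot_alert_report <- function(report, active_line = 1.6) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_alert_report requires the ggplot2 package", call. = FALSE)
  }
  cols <- c(NON_BLOOM = "forestgreen", PRE_ALERT = "gold2",
            ACTIVE_BLOOM = "firebrick", UNKNOWN = "gray70")
  p <- ggplot2::ggplot(report, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_col(data = report[!is.na(report$index), ],
                      ggplot2::aes(y = .data$index, fill = .data$state)) +
    ggplot2::geom_rug(data = report[is.na(report$index), ],
                      ggplot2::aes(color = .data$state), sides = "b") +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::scale_color_manual(values = cols, guide = "none") +
    ggplot2::labs(x = NULL, y = "IOP index (SD units)", fill = "state") +
    ggplot2::theme_minimal()
  if (!is.null(active_line)) {
    p <- p + ggplot2::geom_hline(yintercept = active_line,
                                 linetype = "dashed", color = "firebrick")
  }
  p
}
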