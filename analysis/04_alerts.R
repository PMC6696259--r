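#!/usr/bin/env Rscript
# Stage 4 — operational alerting on the 2017 scoring season.
#
# Each point's new season is scored against its frozen baseline (no refit),
# classified, and run through the conservative gap-holding rule: cloud-gap
# days inherit the last observed state, flagged stale after 14 held days.

suppressPackageStartupMessages(library(bloomindex))
dir.create("results", showWarnings = FALSE)

for (pid in c("P4", "P6")) {
  series <- read_series_csv(sprintf("results/data/%s_2017.csv", pid))
  season <- list()
  for (m in 5:6) {
    bl <- read_baseline_json(sprintf("results/models/%s_month%d_baseline.json", pid, m))
    season[[as.character(m)]] <- compute_index_series(series, bl)
  }
  idx <- do.call(rbind, season)
  idx <- idx[order(idx$date), ]
  log <- hold_state(idx, max_hold_days = 14)
  rep_ <- render_report(log, idx)
  utils::write.csv(rep_, sprintf("results/%s_2017_alerts.csv", pid), row.names = FALSE)

  n_obs <- sum(rep_$provenance %in% "OBSERVED")
  n_held <- sum(rep_$provenance %in% "HELD")
  longest <- if (n_held) max(rep_$days_since_obs, na.rm = TRUE) else 0
  cat(sprintf("%s 2017: %d days, %d observed, %d held (longest gap %d d, %d stale), states: %s\n",
              pid, nrow(rep_), n_obs, n_held, longest, sum(rep_$stale),
              paste(sprintf("%s=%d", names(table(rep_$state)), table(rep_$state)),
                    collapse = " ")))
  reds <- rep_$date[rep_$state == "ACTIVE_BLOOM"]
  if (length(reds)) {
    cat(sprintf("  active-bloom (red) days: %s\n", paste(reds, collapse = ", ")))
  }
}
cat("wrote results/P*_2017_alerts.csv\n")
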