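#!/usr/bin/env Rscript
# Stage 1 — generate the study dataset.
#
# Two monitoring points in a cloudy coastal bay, daily May-June absorption
# pairs over 2003-2016 at ~70% cloud-gap missingness, with multi-day bloom
# events injected only in the early era (2003-2009) so the archive carries a
# trend inversion. A separate May-June 2017 scoring series per point uses
# cloudy-spell missingness, producing the multi-week outages the alerting
# stage has to hold state across. Ground truth is saved alongside.

suppressPackageStartupMessages(library(bloomindex))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

events_p4 <- list(
  bloom_event("2004-05-12", 1, 4.5, "both"),
  bloom_event("2005-05-20", 2, 4.0, "both"),
  bloom_event("2006-05-08", 3, 4.5, "both"),
  bloom_event("2007-06-15", 3, 4.0, "both"),
  bloom_event("2009-06-03", 1, 4.0, "both")
)
events_p6 <- list(
  bloom_event("2003-05-06", 2, 4.5, "both"),
  bloom_event("2005-05-25", 1, 4.0, "both"),
  bloom_event("2007-06-20", 1, 4.0, "cdom"),
  bloom_event("2009-05-10", 1, 4.5, "both")
)

archive <- list(
  P4 = synth_config(years = 2003:2016, months = 5:6, base_mean_aphy = 0.05,
                    base_mean_adcdom = 0.04, cv = 0.4, rho = 0.6,
                    missing_prob = 0.7, bloom_events = events_p4,
                    point_id = "P4", seed = 401),
  P6 = synth_config(years = 2003:2016, months = 5:6, base_mean_aphy = 0.06,
                    base_mean_adcdom = 0.045, cv = 0.4, rho = 0.6,
                    missing_prob = 0.7, bloom_events = events_p6,
                    point_id = "P6", seed = 601)
)

for (pid in names(archive)) {
  sim <- simulate_series(archive[[pid]])
  write_series_csv(sim$series, sprintf("results/data/%s_archive.csv", pid))
  utils::write.csv(sim$truth, sprintf("results/data/%s_truth.csv", pid), row.names = FALSE)
  obs <- sum(pair_complete(sim$series))
  cat(sprintf("%s archive: %d calendar days, %d observed (%.0f%%), %d injected bloom days\n",
              pid, nrow(sim$series), obs, 100 * obs / nrow(sim$series), nrow(sim$truth)))
}

# 2017 scoring season: cloudy spells + one active bloom mid-June at P6
score <- list(
  P4 = synth_config(years = 2017, months = 5:6, base_mean_aphy = 0.05,
                    base_mean_adcdom = 0.04, cv = 0.4, rho = 0.6,
                    missing_prob = 0.6, missing_mode = "spells",
                    mean_spell_length = 5, point_id = "P4", seed = 417),
  P6 = synth_config(years = 2017, months = 5:6, base_mean_aphy = 0.06,
                    base_mean_adcdom = 0.045, cv = 0.4, rho = 0.6,
                    missing_prob = 0.6, missing_mode = "spells",
                    mean_spell_length = 5, point_id = "P6", seed = 617,
                    bloom_events = list(bloom_event("2017-06-14", 2, 4.5, "both")))
)
for (pid in names(score)) {
  sim <- simulate_series(score[[pid]])
  write_series_csv(sim$series, sprintf("results/data/%s_2017.csv", pid))
  cat(sprintf("%s 2017 season: %d days, %d observed\n", pid,
              nrow(sim$series), sum(pair_complete(sim$series))))
}
cat("wrote results/data/\n")
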