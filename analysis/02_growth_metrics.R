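#!/usr/bin/env Rscript

# Reduce both simulated screens to per-well growth summaries: AUC
# (sum-over-timepoints convention), the cell line's shared exponential-phase
# cutoff, slopes, and control-relative versions. Also writes day 0-4 /
# day 4-8 windowed AUC metrics for the CIN screen, which the windowed synergy
# analysis reuses.

library(cinsynergy)

for (screen_name in c("aneuploidy", "cin")) {
  screen <- read_screen_table(sprintf("scratch/screen_%s.csv", screen_name))
  metrics <- screen_metrics(screen)
  write_stage_csv(metrics, sprintf("scratch/metrics_%s.csv", screen_name),
                  "metrics")
  message(sprintf("%s: %d wells; cutoff times (h): %s", screen_name,
                  nrow(metrics),
                  paste(unique(metrics$cutoff_time), collapse = ", ")))
}

cin <- read_screen_table("scratch/screen_cin.csv")
windows <- split_time_windows(cin, 4)
for (w in names(windows)) {
  m <- screen_metrics(windows[[w]], slopes = FALSE)
  m$window <- w
  write_stage_csv(m, sprintf("scratch/metrics_cin_%s.csv", gsub("-", "_", w)),
                  "metrics")
}
message("windowed CIN metrics written for: ", paste(names(windows), collapse = ", "))
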