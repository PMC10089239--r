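#!/usr/bin/env Rscript
# Frequency tagging and brain-stimulus synchronization on the paper-like
# synthetic cohort.
#
# Generates the reduced-size stand-in for the study cohort (17 participants,
# 50 trials per rhythm, steady-state components of 0.3 uV at the meter
# frequencies and 0.5 uV at the beat over 10 uV RMS 1/f noise, von Mises
# kappa = 5 between-participant phase lags), runs the full analysis, and
# prints the group-level tables: amplitudes vs noise floor, beat-normalised
# enhancement vs the stimulus envelope, and per-electrode phase-lag
# consistency. Expected outcome: every injected beat/meter frequency sits
# significantly above the noise floor, the duple-meter normalised response
# exceeds the stimulus value, and SI angles are consistent across
# participants at every analysed frequency.

library(rhythmtag)

seed <- 1
args <- commandArgs(trailingOnly = TRUE)
if (length(args)) seed <- as.integer(args[1])

cfg <- scaled_study_config(seed = seed)
res <- run_pipeline(cfg, out_dir = "results/cohort", verbose = TRUE)
report(res)

rs <- recovery_summary(res)
cat("\nGround-truth lag recovery under the full noise model:\n")
print(format(rs[, c("rhythm", "freq_hz", "lag_true_deg", "lag_recovered_deg",
                    "lag_error_deg", "mean_si")], digits = 3),
      row.names = FALSE)
write.table(rs, "results/cohort/recovery_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\ntables in results/cohort\n")
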