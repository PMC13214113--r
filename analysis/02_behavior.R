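#!/usr/bin/env Rscript
# Step 2: extract behavioral variables from the luxmeter/accelerometer
# traces and run the condition comparisons.
#
# RT = go cue to first luminosity peak; MT = mean of the four inter-peak
# intervals; amplitude = per-repetition luminosity range; mean |acc| from
# go cue to the last peak. Outliers (3 raw MADs from the median, per
# subject x condition x variable) are flagged and excluded from means.

suppressMessages(library(betavigor))

cohort <- read_cohort("results/cohort")
subjects <- cohort$truth$subjects$subject

behav <- do.call(rbind, lapply(seq_along(subjects), function(s)
  behavior_table(cohort$subjects[[s]]$kinematics, subjects[s])))
write.csv(behav, "results/behavior_trials.csv", row.names = FALSE)

bsum <- summarize_behavior(behav)
write.csv(bsum$summary, "results/behavior_summary.csv", row.names = FALSE)
write.csv(bsum$diffs, "results/behavior_diffs.csv", row.names = FALSE)

for (v in c("MT", "RT", "amplitude", "mean_abs_acc")) {
  f <- bsum$summary[bsum$summary$condition == "Fast", ]
  s <- bsum$summary[bsum$summary$condition == "Slow", ]
  r <- paired_compare(f[[v]][match(subjects, f$subject)],
                      s[[v]][match(subjects, s$subject)])
  cat(sprintf("%-14s %-9s stat=%8.3f p=%.2e %s=%6.2f\n", v, r$test,
              r$statistic, r$p, r$effect_type, r$effect_size))
}
cat("Fast trials should show shorter MT and RT than Slow: see above.\n")
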