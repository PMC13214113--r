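#!/usr/bin/env Rscript
# Step 5: subject-specific decoding of Fast vs Slow.
#
# Grouped sequential forward selection (each group = one parcel/channel
# with its 7 windows; gain threshold 0.002; at most 3 groups) around an
# L1 logistic model in leakage-safe stratified 5-fold CV, then 1000
# bootstrap resamples of the frozen selection for the AUC CI. Negative
# coefficients mean the feature is lower in Fast trials.

suppressMessages(library(betavigor))

cohort <- read_cohort("results/cohort")
band <- beta_band("standard")
subjects <- cohort$truth$subjects$subject
seed <- 20260922L

decode_path <- function(make_tensor, candidates, tag) {
  res <- lapply(seq_along(subjects), function(s) {
    tens <- make_tensor(s)
    cand <- candidate_preset(candidates, tens$unit_ids)
    suppressMessages(decode_subject(tens, cand, n_boot = 1000,
                                    seed = fan_seed(seed, 1000L + s),
                                    subject = subjects[s]))
  })
  tab <- data.frame(
    subject = subjects,
    mean_auc = vapply(res, `[[`, 0, "mean_auc"),
    ci_lo = vapply(res, function(r) r$bootstrap_ci[1], 0),
    ci_hi = vapply(res, function(r) r$bootstrap_ci[2], 0),
    mean_coefficient = vapply(res, `[[`, 0, "mean_coefficient"),
    above_chance = vapply(res, `[[`, TRUE, "above_chance"),
    selected = vapply(res, function(r) paste(r$selected_groups,
                                             collapse = "+"), ""))
  write.csv(tab, sprintf("results/decoding_%s.csv", tag), row.names = FALSE)
  freq <- selection_frequency(res, candidate_preset(candidates,
                                                    make_tensor(1)$unit_ids))
  write.csv(freq, sprintf("results/selection_%s.csv", tag), row.names = FALSE)
  cat(tag, ": mean dAUC", round(mean(tab$mean_auc) - 0.5, 3), "|",
      sum(tab$above_chance), "above chance | most selected:",
      paste(head(freq$unit, 3), collapse = ", "), "\n")
  tab
}

decode_path(function(s)
  source_features(cohort$subjects[[s]]$parcels, band, "icoh")$icoh,
  "fronto-parietal-21", "icoh")
decode_path(function(s)
  morlet_band_power(cohort$subjects[[s]]$epochs, band),
  "left-central-21", "power")
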