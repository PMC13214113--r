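#!/usr/bin/env Rscript
# Step 3: compute the feature tensors.
#
# Sensor space: Morlet band power (7 cycles, 1 Hz steps across the band)
# averaged in the seven 0.5 s windows around the go cue. Source space:
# zero-phase FIR band-pass, decimation to 128 Hz, per-trial symmetric
# orthogonalization, Hilbert transform, and seed-based imaginary
# coherence with every other parcel. Long-format CSVs go to results/.

suppressMessages(library(betavigor))

cohort <- read_cohort("results/cohort")
band <- beta_band("standard")
subjects <- cohort$truth$subjects$subject

long <- function(tens, subject) {
  d <- dim(tens$values)
  data.frame(subject = subject,
             trial = rep(seq_len(d[1]), d[2] * d[3]),
             unit = rep(rep(tens$unit_ids, each = d[1]), d[3]),
             window = rep(seq_len(d[3]), each = d[1] * d[2]),
             condition = rep(tens$labels, d[2] * d[3]),
             value = as.vector(tens$values))
}

icoh_rows <- list(); power_rows <- list()
for (s in seq_along(subjects)) {
  sf <- source_features(cohort$subjects[[s]]$parcels, band, "icoh")
  icoh_rows[[s]] <- long(sf$icoh, subjects[s])
  mp <- morlet_band_power(cohort$subjects[[s]]$epochs, band)
  power_rows[[s]] <- long(mp, subjects[s])
  cat("subject", subjects[s], "done\n")
}
write.csv(do.call(rbind, icoh_rows), "results/features_icoh.csv",
          row.names = FALSE)
write.csv(do.call(rbind, power_rows), "results/features_power.csv",
          row.names = FALSE)
cat("Feature tensors -> results/features_{icoh,power}.csv\n")
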