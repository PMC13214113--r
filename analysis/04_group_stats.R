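#!/usr/bin/env Rscript
# Step 4: group-level maps and tests.
#
# Trials are screened cell-wise by the 3xMAD rule before across-trial
# averaging. Sensor power: paired cluster-based permutation tests per
# window over the channel adjacency graph. Source coherence: per-parcel
# paired t maps, top-parcel ranking, and the sign-proportion permutation
# test over the fronto-parietal subset.

suppressMessages(library(betavigor))

cohort <- read_cohort("results/cohort")
rc <- run_config(seed = 20260922, analyses = c("source-icoh", "sensor-power"))
band <- beta_band(rc$band)
subjects <- cohort$truth$subjects$subject
n_sub <- length(subjects)

get_means <- function(make_tensor) {
  lapply(seq_len(n_sub), function(s) {
    sc <- screen_trials(make_tensor(s))
    tensor_condition_means(sc$tensor)
  })
}

## source coherence maps
cm <- get_means(function(s)
  source_features(cohort$subjects[[s]]$parcels, band, "icoh")$icoh)
units <- rownames(cm[[1]]$Fast)
tmat <- vapply(seq_len(7), function(w) {
  d <- t(vapply(cm, function(m) m$Fast[, w] - m$Slow[, w],
                numeric(length(units))))
  colMeans(d) / (apply(d, 2, sd) / sqrt(n_sub))
}, numeric(length(units)))
rownames(tmat) <- units
write.csv(tmat, "results/icoh_tmap.csv")
cat("Top parcels by |mean t| (Fast vs Slow iCoh):\n")
print(rank_parcels_by_t(tmat, 5))

subset <- candidate_preset("fronto-parietal-21", units)
dmean <- t(vapply(cm, function(m)
  rowMeans(m$Fast[subset, ] - m$Slow[subset, ]), numeric(length(subset))))
sp <- sign_proportion_permutation(dmean, n_perm = 1000, seed = 7)
cat(sprintf("Sign proportion (Fast<Slow): %.2f, z=%.2f, p=%.3f\n",
            sp$prop_negative, sp$z, sp$p))

## sensor power cluster tests
cmp <- get_means(function(s)
  morlet_band_power(cohort$subjects[[s]]$epochs, band))
chan <- rownames(cmp[[1]]$Fast)
adj <- build_adjacency(cohort$subjects[[1]]$epochs$positions, 0.02)
for (w in seq_len(7)) {
  a <- t(vapply(cmp, function(m) m$Fast[, w], numeric(length(chan))))
  b <- t(vapply(cmp, function(m) m$Slow[, w], numeric(length(chan))))
  r <- paired_cluster_permutation(a, b, adj, n_perm = 1000, seed = 100 + w)
  sig <- sum(r$p_values < 0.05)
  cat(sprintf("window %d: %d cluster(s), %d significant\n",
              w, length(r$p_values), sig))
}
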