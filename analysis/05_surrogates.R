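#!/usr/bin/env Rscript
# Validation against temporally shuffled data: for the 30-subject synthetic
# cohort, compare totGEV of each real recording with 10 per-channel-rotated
# surrogates (models refitted per surrogate), after scaled-MAD outlier
# screening, with KS statistics.

suppressPackageStartupMessages(library(ratstates))

manifest <- read.csv("results/data/cohort_manifest.csv")
recs <- lapply(seq_len(nrow(manifest)), function(i) {
  m <- manifest[i, ]
  simulate_dataset(n_channels = m$n_channels, n_states = m$n_states,
                   duration_s = m$duration_s, fs = m$fs, snr = m$snr,
                   seed = m$seed)
})

gc_ <- gev_contrast(recs, k = 5, n_repeats = 10, seed = 20260929)
print(gc_)

tab <- rbind(
  data.frame(group = "real", totgev = gc_$real_gevs, kept = gc_$real_mask),
  data.frame(group = "surrogate", totgev = gc_$surrogate_gevs,
             kept = gc_$surrogate_mask))
write.csv(tab, "results/gev_contrast_values.csv", row.names = FALSE)

summary <- list(
  k = 5,
  real_mean = gc_$real_mean, real_sd = gc_$real_sd,
  surrogate_mean = gc_$surrogate_mean, surrogate_sd = gc_$surrogate_sd,
  ks_two_sample_D = unname(gc_$tests$two_sample$statistic),
  ks_two_sample_p = gc_$tests$two_sample$p.value)
jsonlite::write_json(summary, "results/gev_contrast_summary.json",
                     auto_unbox = TRUE, digits = NA)
cat("\nShuffling collapses totGEV by",
    sprintf("%.2f", gc_$real_mean - gc_$surrogate_mean),
    "- microstate structure in the cohort is non-random.\n")
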