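#!/usr/bin/env Rscript
# How many microstate classes? Score K = 1..10 with every implemented
# criterion on the reference recording and report each criterion's vote
# plus the median metacriterion. KL is the preferred criterion.

suppressPackageStartupMessages(library(ratstates))

rec <- read_recording("results/data/reference_preprocessed.csv")
fit <- fit_microstates(rec, k_min = 1, k_max = 10)
pk <- attr(fit, "gfp")$peak_indices
peaks <- t(average_reference(rec)$data[, pk])

tab <- criterion_table(peaks, fit)
write.csv(tab, "results/criterion_table.csv", row.names = FALSE)

votes <- attr(tab, "chosen_k")
cat("Criterion votes for the optimal K:\n")
print(votes)
cat("KL choice:", votes[["kl"]],
    "| metacriterion (median vote):", metacriterion_select(tab), "\n")
cat("\nPer-K scores written to results/criterion_table.csv\n")
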