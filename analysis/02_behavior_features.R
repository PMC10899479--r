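#!/usr/bin/env Rscript

# Step 2 — behavioral measures and cleaning.
#
# Attaches discrepancy (absolute difference between the two members'
# estimates), its min-max scaled version (constants from the first-feedback
# distribution), the per-participant adjustment after each feedback, and the
# per-trial accuracy of the dyad's final midpoint; then applies the P95
# outlier rule (replace with NA).

library(dyadconv)

beh <- read_behavior_csv("results/data/behavior.csv")
stim <- read.csv("results/data/stimuli.csv")

beh <- compute_discrepancy(beh)
beh <- scale_discrepancy(beh)
beh <- compute_adjustment(beh)
beh <- compute_accuracy(beh, stim)
beh <- clean_responses(beh, "discrepancy", 95, action = "na")
cat(sprintf("P95 cleaning replaced %d discrepancy values with NA\n",
            attr(beh, "n_removed")))

write_behavior_csv(beh, "results/behavior_features.csv")
m <- tapply(beh$discrepancy, beh$feedback_index, mean, na.rm = TRUE)
z <- tapply(beh$discrepancy == 0, beh$feedback_index, mean, na.rm = TRUE)
cat(sprintf("mean discrepancy by feedback: %.2f -> %.2f -> %.2f\n", m[1], m[2], m[3]))
cat(sprintf("exact-agreement fraction:     %.2f -> %.2f -> %.2f\n", z[1], z[2], z[3]))
cat(sprintf("mean final accuracy: %.2f units\n",
            mean(beh$accuracy[beh$feedback_index == 3], na.rm = TRUE)))
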