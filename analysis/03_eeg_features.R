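#!/usr/bin/env Rscript

# Step 3 — EEG features.
#
# Baseline-corrects the epochs (-100..0 ms), rejects any epoch exceeding
# +/- 100 uV between -100 and 1000 ms, and extracts (a) ERP mean amplitudes in
# the four analysis windows at Fz/Cz/Pz and (b) Morlet band power (theta,
# alpha, beta) normalized by the -400..-100 ms baseline in the early and late
# time-frequency windows.

library(dyadconv)

epochs <- read_epochs("results/data/epochs")
epochs <- apply_baseline(epochs, c(-0.1, 0))
epochs <- reject_artifacts(epochs, threshold_uv = 100)
cat(sprintf("rejected %d of %d epochs at +/-100 uV\n",
            sum(epochs$rejected), n_epochs(epochs)))

erp <- add_cell_column(erp_window_means(epochs))
write.csv(erp, "results/erp_features.csv", row.names = FALSE)
cat(sprintf("ERP features: %d rows (%d epochs x 3 electrodes x 4 windows)\n",
            nrow(erp), sum(!epochs$rejected)))

tf <- add_cell_column(tf_band_features(epochs, freqs = 2:30))
write.csv(tf, "results/tf_features.csv", row.names = FALSE)
cat(sprintf("TF features: %d rows; grand-mean power ratios by band:\n", nrow(tf)))
print(round(tapply(tf$value, tf$band, mean), 3))
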