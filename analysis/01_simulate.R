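#!/usr/bin/env Rscript

# Step 1 — simulate the study.
#
# Generates a Study-2-style dataset: 18 dyads x 100 trials (four blocks of 25)
# of the line-and-point estimation task, three feedback repetitions per trial,
# plus synthetic EEG epochs around every feedback event with the planted
# frontocentral negativity, late positivity, and band-power modulations over
# 1/f background noise. A reduced sampling rate keeps the epoch container
# small; the generator itself defaults to the acquisition rate (1024 Hz).

library(dyadconv)

seed <- as.integer(Sys.getenv("DYADCONV_SEED", "1"))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_study(18, 100, 4, agent_params(2, 0.3, 0.1), seed = seed)
write_behavior_csv(sim$behavior, file.path(out, "behavior.csv"))
write.csv(sim$stimuli, file.path(out, "stimuli.csv"), row.names = FALSE)
cat(sprintf("behavior: %d rows (%d dyads, %d trials each)\n",
            nrow(sim$behavior), length(unique(sim$behavior$dyad_id)), 100))

# EEG for a subset of dyads keeps the demonstration light; every epoch is one
# participant x trial x feedback event
sub <- sim$behavior[sim$behavior$dyad_id <= 5, ]
beh <- compute_adjustment(scale_discrepancy(compute_discrepancy(sub)))
gen <- eeg_gen_params(sampling_rate = 256, noise_scale = 5, seed = seed + 1)
epochs <- simulate_eeg_epochs(beh, gen)
epochs <- inject_artifacts(epochs, fraction = 0.02, amplitude_uv = 150,
                           seed = seed + 2)
write_epochs(epochs, file.path(out, "epochs"))
cat(sprintf("epochs: %d (%.1f%% with injected artifacts) at %g Hz\n",
            n_epochs(epochs), 100 * mean(epochs$events$artifact_injected),
            epochs$sfreq))
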