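#!/usr/bin/env Rscript

# Step 4 — hierarchical Bayesian model fits.
#
# Fits the two headline models at test-scale MCMC settings: the hurdle-gamma
# discrepancy-by-feedback model with feedback random slopes for participants
# nested in dyads, and the Student-t single-trial ERP model with the scaled
# discrepancy x feedback interaction and uncorrelated random slopes per
# time-window x electrode cell. Posterior draws for the reported contrasts are
# written for the decision step.

library(dyadconv)

seed <- as.integer(Sys.getenv("DYADCONV_SEED", "1"))
dir.create("results/fits", showWarnings = FALSE, recursive = TRUE)

beh <- read_behavior_csv("results/behavior_features.csv")
fit_beh <- sample_posterior(model_spec("feedback-simple"), beh,
                            sampler_settings(chains = 4, iterations = 1500,
                                             warmup = 500, seed = seed))
cc <- check_convergence(fit_beh)
cat(sprintf("feedback-simple: %d rows, max split R-hat %.3f (converged: %s)\n",
            fit_beh$meta$n, cc$max_rhat, cc$converged))
beh_draws <- data.frame(contrast = rep(c("fb2-fb1", "fb3-fb2"),
                                       each = length(contrast(fit_beh, "fb2-fb1"))),
                        draw = c(contrast(fit_beh, "fb2-fb1"),
                                 contrast(fit_beh, "fb3-fb2")))
write.csv(beh_draws, "results/fits/behavior_contrast_draws.csv", row.names = FALSE)
writeLines(as.character(sd(fit_beh$meta$response)), "results/fits/behavior_sdy.txt")

erp <- read.csv("results/erp_features.csv")
erp <- merge_signal_features(erp, beh)
erp <- clean_responses(filter_converged_trials(erp), "value", 95, action = "drop")
cat(sprintf("ERP model data: %d rows after converged-trial and P95 filters\n", nrow(erp)))
fit_erp <- sample_posterior(model_spec("discrepancy-fb"), erp,
                            sampler_settings(chains = 2, iterations = 2000,
                                             warmup = 700, seed = seed + 1))
cc2 <- check_convergence(fit_erp)
cat(sprintf("discrepancy-fb: max split R-hat %.3f (converged: %s)\n",
            cc2$max_rhat, cc2$converged))
cells <- sort(unique(erp$cell))
rows <- lapply(cells, function(cell) {
  data.frame(cell = cell,
             draw = contrast(fit_erp, "covariate-max-vs-min", feedback = 1,
                             cell = cell),
             sdy = sd(fit_erp$meta$response[fit_erp$meta$cell == cell]))
})
write.csv(do.call(rbind, rows), "results/fits/erp_contrast_draws.csv",
          row.names = FALSE)
cat("wrote contrast draws for", length(cells), "cells\n")
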