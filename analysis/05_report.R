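#!/usr/bin/env Rscript

# Step 5 — HDI + ROPE decisions and the report.
#
# For every stored contrast: the 95% highest density interval, a region of
# practical equivalence of +/- 0.05 SDy (behavioral/ERP scale), HDI endpoints
# rounded to two decimals, and the three-way decision. A contrast is credible
# only when the entire rounded HDI falls outside the ROPE.

library(dyadconv)

beh_draws <- read.csv("results/fits/behavior_contrast_draws.csv")
sdy_beh <- as.numeric(readLines("results/fits/behavior_sdy.txt"))
decisions <- list()
for (cn in unique(beh_draws$contrast)) {
  d <- beh_draws$draw[beh_draws$contrast == cn]
  decisions[[length(decisions) + 1]] <-
    decide(hdi(d), c(-0.05, 0.05) * sdy_beh, 2,
           contrast_name = paste0("feedback-simple:", cn), sdy = sdy_beh)
}

erp_draws <- read.csv("results/fits/erp_contrast_draws.csv")
for (cell in unique(erp_draws$cell)) {
  d <- erp_draws[erp_draws$cell == cell, ]
  decisions[[length(decisions) + 1]] <-
    decide(hdi(d$draw), c(-0.05, 0.05) * d$sdy[1], 2,
           contrast_name = "discrepancy-fb:max-vs-min@fb1", cell = cell,
           sdy = d$sdy[1])
}

report <- summarize_decisions(decisions, model = "dyadconv-analysis")
write.csv(report, "results/decisions.csv", row.names = FALSE)
writeLines(dyadconv:::format_report(report), "results/report.txt")
cat(readLines("results/report.txt"), sep = "\n")
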