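#!/usr/bin/env Rscript
# Segments the simulated plate into the 25 behavioral endpoints and tests
# every group against the colonized vehicle control with the pooled
# median-difference bootstrap (BH-corrected family of 125 tests). Expects
# the outputs of 01_simulate_behavior.R; writes endpoint and test tables
# under results/behavior_analysis/.

library(vamrbiome)

act <- "results/behavior_data/activity.tsv"
meta <- "results/behavior_data/metadata.tsv"
if (!file.exists(act)) stop("run analysis/01_simulate_behavior.R first")

res <- run_behavior_pipeline(
  act, meta, "results/behavior_analysis",
  control = "colonized_control",
  config = bootstrap_config(B_test = 2000L, B_ci = 1000L, seed = 20260901L))

tests <- res$tests
sig <- tests[tests$p_adj < 0.05, ]
cat("Tested", nrow(tests), "endpoint x group comparisons;",
    nrow(sig), "significant after BH.\n")
if (nrow(sig) > 0) {
  print(as.data.frame(sig[, c("endpoint", "comparison", "observed_stat",
                              "p_raw", "p_adj")]), row.names = FALSE)
}
cat("Endpoint table and test results written under",
    "results/behavior_analysis/\n")
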