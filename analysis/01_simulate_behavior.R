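#!/usr/bin/env Rscript
# Generates the synthetic behavioral dataset used by the downstream analysis
# steps: a six-group plate (two colonization cohorts x three exposure groups,
# 45 wells each) with a dark-phase hyperactivity effect injected into the
# colonized high-concentration group and accelerated within-bout habituation
# in all azoxystrobin-exposed groups. Writes the activity table, plate
# metadata and ground truth under results/behavior_data/.

library(vamrbiome)

groups <- default_behavior_groups()
groups$hyperactivity[groups$group == "colonized_high"] <- 1.9
groups$hab_accel[grepl("low|high", groups$group)] <- 1.6
spec <- behavior_sim_spec(groups = groups, seed = 20260901L)

paths <- write_simulated_datasets("results/behavior_data",
                                  behavior_spec = spec)
cat("Simulated", nrow(groups), "groups x", groups$n_wells[1], "wells;",
    "injected hyperactivity multiplier",
    groups$hyperactivity[groups$group == "colonized_high"],
    "in colonized_high.\n")
cat("Wrote:", unlist(paths), sep = "\n  ")
cat("\n")
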