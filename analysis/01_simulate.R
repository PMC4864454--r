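#!/usr/bin/env Rscript
# Stage 1: generate the synthetic four-taxon dataset used throughout the
# analysis: a 2 Mb CpG-depleted ancestral genome, background substitutions on
# every branch of ((target,sister),outgroup1,outgroup2), 300 planted A3G
# cluster events on the target branch (80% at CCC, spacing 11-50 bp, both
# strands), lineage allele tracks, and annotation tracks. Everything is
# written as plain-text fixture files for the downstream stages.

library(a3gclust)

cfg <- simulation_config(
  genome_length = 2e6, seed = 20260920,
  branch_rates = c(target = 1e-3, sister = 1e-3, internal = 2e-3,
                   outgroup1 = 0.02, outgroup2 = 0.06),
  a3g_event_rate = 300 / 2e6, motif_fidelity = 0.8)

sim <- simulate_dataset(cfg)
paths <- write_fixture(sim, "results/fixture")

n_events <- length(unique(sim$truth$event_id[sim$truth$event_class == "a3g"]))
cat(sprintf("Simulated %d bp genome (seed %d).\n", cfg$genome_length, cfg$seed))
cat(sprintf("Target-branch truth: %d mutations total; %d planted A3G events (%d mutations), %d CpG-driven, %d other background.\n",
            nrow(sim$truth), n_events, sum(sim$truth$event_class == "a3g"),
            sum(sim$truth$event_class == "cpg"),
            sum(sim$truth$event_class == "background")))
cat(sprintf("Lineage assignment of target mutations: %s.\n",
            paste(names(table(sim$truth$lineage)),
                  table(sim$truth$lineage), sep = "=", collapse = ", ")))
cat("Fixture files:\n")
for (p in paths) cat(" -", p, "\n")
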