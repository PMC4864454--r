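#!/usr/bin/env Rscript
# Stage 5: functional-region analyses. A transcription-coupled dataset is
# simulated (A3G events planted inside expression intervals with probability
# proportional to their level), the A3G-induced mutation set is compared
# with the control set across annotation tracks, per-expression-decile
# fold-changes are correlated with level, and the branch comparison contrasts
# common-branch and modern-lineage A3G mutations across region families.

library(a3gclust)

cfg <- simulation_config(
  genome_length = 6e6, seed = 20260921,
  branch_rates = c(target = 1e-3, sister = 1e-3, internal = 2e-3,
                   outgroup1 = 0.02, outgroup2 = 0.06),
  a3g_event_rate = 2000 / 6e6, a3g_weight_by = "expression")
sim <- simulate_dataset(cfg)
ms <- call_mutations(sim$alignment, masks = sim$annotations["repeat_mask"])
cs <- classify_clusters(exclude_complex(detect_clusters(ms)))
a3g <- define_a3g_clusters(cs)$mutations
ctrl <- ms$mutations[!(ms$mutations$pos0 %in% a3g$pos0), ]
cat(sprintf("A3G-induced set: %d mutations; control set: %d mutations.\n",
            nrow(a3g), nrow(ctrl)))

region_panel <- sim$annotations[c("transcribed", "exons", "regulatory",
                                  "expression")]
fc <- region_panel_fold_change(a3g, ctrl, region_panel)
write.table(fc, "results/region_fold_change.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Fold-change of A3G vs control mutations by region (Bonferroni q):\n")
print(fc[, c("label", "a3g_in", "control_in", "fold_change", "q")], digits = 3)

dec <- expression_decile_correlation(a3g, ctrl, sim$annotations$expression)
write.table(dec$deciles, "results/expression_deciles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nPer-decile fold-change vs expression level: r = %.2f over deciles 1-9; top decile fold-change %.2f (reported separately).\n",
            dec$r, dec$top_decile$fold_change))
cat("(The pipeline control set still contains planted mutations whose\n")
cat("clusters were lost to N-typing; they attenuate the decile gradient\n")
cat("relative to a truth-purified control.)\n")

# branch comparison: common-branch vs modern-lineage A3G mutations
part <- partition_by_lineage(a3g, sim$tracks)
branch_a <- part[part$lineage == "common", ]
branch_b <- part[part$lineage == "modern", ]
cat(sprintf("\nBranch comparison: %d common-branch vs %d modern-lineage A3G mutations.\n",
            nrow(branch_a), nrow(branch_b)))
bc <- branch_comparison(region_panel, branch_a, branch_b,
                        control_a = ctrl, control_b = ctrl)
write.table(bc, "results/branch_comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(bc[, c("family", "a_in", "b_in", "fold_change_a", "fold_change_b",
             "direction", "p", "q")], digits = 3)
cat("With lineage labels assigned at random in the generator, no family\n")
cat("should show differential accumulation beyond chance.\n")
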