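#!/usr/bin/env Rscript
# Full pipeline on a synthetic cohort with planted effects.
#
# Runs the complete chain — per-subject cleanup, Pearson connectivity with
# 20 mm exclusion, proportional thresholding at 1-30 %, stability-selected
# group decomposition (Louvain + fine-tuning, best of 50 seeds), weighted
# measure curves, and AUC permutation tests for both polymorphisms — on a
# seeded cohort of 111 subjects with 120 ROIs in 6 planted modules.
#
# Findings (seed 103/104): the decomposition recovers the planted 6 modules
# exactly; the S-carrier group shows the planted negative participation
# shift in the designated modules, and the COMT risk group the planted
# negative neuroticism slope for local efficiency in the moderated modules.

library(neurogenet)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_subjects = 111, n_rois = 120, n_volumes = 300)
cohort <- simulate_cohort(cfg, seed = 103)
res <- run_pipeline(cohort, n_perm = 1000, seed = 104)
rs <- recovery_summary(res, cohort)

cat(sprintf("selected density: %.2f\n", res$selected_density))
cat(sprintf("modules detected: %d (exact recovery: %s)\n",
            rs$n_modules, rs$exact_recovery))
cat(sprintf("subjects excluded by scrubbing: %d\n", length(res$excluded)))
cat("participation AUC (risk - non-risk), designated modules:\n")
print(rs$participation_auc)
cat("local-efficiency slope AUC (risk - non-risk), moderated modules:\n")
print(rs$slope_auc)

write_partition_tsv(res$partition, cohort$coords$roi_id,
                    "results/partition.tsv")
write.table(res$inference_httlpr, "results/inference_httlpr.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$inference_comt, "results/inference_comt.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
summ <- data.frame(
  selected_density = res$selected_density,
  n_modules = rs$n_modules,
  exact_recovery = rs$exact_recovery,
  participation_auc_mean = mean(rs$participation_auc),
  slope_auc_mean = mean(rs$slope_auc))
write.table(summ, "results/pipeline_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nwrote results/partition.tsv, inference_*.tsv, pipeline_summary.tsv\n")
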