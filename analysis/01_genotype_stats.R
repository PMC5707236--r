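#!/usr/bin/env Rscript
# Genotype-level statistics for the studied cohort.
#
# The genotype counts printed in the study report are sufficient to
# reproduce every genotype-level statistic: allele frequencies, 1-df
# Hardy-Weinberg chi-square p-values, and the risk-group sizes. This script
# recomputes them from those counts and, as a check of the phasing
# machinery, runs the two-marker EM haplotype estimator on a synthetic
# cohort drawn at the same allele frequencies with moderate linkage
# disequilibrium.
#
# Findings: HWE p-values 0.58 / 0.67 / 0.90 and allele frequencies
# 0.50 / 0.53 / 0.69 match the published table at 2 decimals; the S-carrier
# versus L-homozygote split of the printed counts is 89 / 31 before
# post-fMRI exclusions (the analyzed sample reports 80 / 31).

library(neurogenet)
dir.create("results", showWarnings = FALSE)

# printed genotype counts: (aa, ab, bb) with a = L, Met, A respectively
counts <- data.frame(
  marker = c("httlpr", "rs4680", "rs165599"),
  allele_a = c("L", "Met", "A"),
  n_aa = c(31, 34, 56), n_ab = c(57, 57, 51), n_bb = c(32, 28, 11))

stats <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
  with(counts[i, ], {
    fr <- allele_frequencies(n_aa, n_ab, n_bb)
    hw <- hwe_chisq_test(n_aa, n_ab, n_bb)
    data.frame(marker = marker, allele_a = allele_a,
               freq_a = round_half_up(fr[["freq_a"]]),
               hwe_chisq = round_half_up(hw$statistic, 3),
               hwe_p = round_half_up(hw$p_value))
  })
}))
write.table(stats, "results/genotype_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(stats)

# risk-group sizes implied by the printed 5-HTTLPR counts
cat(sprintf("\nS-carriers: %d, L-homozygotes: %d (printed counts, n = 120)\n",
            57 + 32, 31))

# EM phasing sanity run on a synthetic cohort with LD between the COMT SNPs
cfg <- sim_config(n_subjects = 500, ld_d = 0.10)
geno <- simulate_genotypes(cfg, seed = 42)
ph <- em_phase_two_markers(geno)
cat("\nEM haplotype frequencies (synthetic cohort, D = 0.10):\n")
print(round(ph$haplotype_freqs, 4))
cat(sprintf("assigned: %d of %d (posterior > 0.80)\n",
            sum(ph$per_subject$assigned), nrow(geno)))
groups <- assign_risk_groups(geno)
cat("\nrisk-group table (synthetic):\n")
print(table(groups$httlpr_group, groups$comt_group))
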